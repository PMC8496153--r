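#' Weighted undirected gene network
#'
#' Constructs the network container used throughout the package: an
#' undirected, weighted graph over gene identifiers. Self-loops are dropped,
#' duplicate edges (in either orientation) are collapsed keeping the maximum
#' weight, and no isolated nodes are retained (the node set equals the set of
#' edge endpoints). Gene identifiers are opaque, case-sensitive strings.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (positive).
#' @param source_tag label identifying the origin network (e.g. "string").
#' @return An object of class `umg_network` wrapping an igraph graph with a
#'   `weight` edge attribute and lexicographically ordered vertices.
#' @export
umg_network <- function(edges, source_tag = "network") {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3)
  edges <- edges[, 1:3]
  names(edges) <- c("from", "to", "weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) stop("non-numeric edge weights")
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) == 0) stop("network has no edges after dropping self-loops")
  verts <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "max"))
  structure(list(graph = g, source_tag = source_tag), class = "umg_network")
}

#' @export
print.umg_network <- function(x, ...) {
  cat(sprintf("umg_network '%s': %d nodes, %d edges\n",
              x$source_tag, network_size(x), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node identifiers of a network
#' @param net `umg_network`.
#' @return Character vector of gene identifiers, lexicographically sorted.
#' @export
network_nodes <- function(net) {
  sort(igraph::V(net$graph)$name)
}

#' Number of nodes
#' @param net `umg_network`.
#' @export
network_size <- function(net) {
  igraph::vcount(net$graph)
}

#' Edge table of a network
#' @param net `umg_network`.
#' @return data.frame with columns `from`, `to`, `weight`; each undirected
#'   edge appears once with `from` < `to`.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  w <- igraph::E(net$graph)$weight
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  out <- data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a weighted edge list from a TSV file
#'
#' Reads 3-column TSV edge lists in the layouts used by common interaction
#' databases: `string_style` (node, node, combined confidence score, often on
#' a 0-1000 integer scale), `humannet_style` (node, node, log-likelihood
#' score) or `generic_tsv`. A header line is detected by a non-numeric third
#' field and skipped. Duplicate edges are collapsed keeping the maximum
#' weight and self-loops are dropped.
#'
#' @param path file path.
#' @param dialect one of "string_style", "humannet_style", "generic_tsv".
#'   Currently all dialects parse identically; the dialect is recorded as the
#'   network's `source_tag` so downstream filters can pick the appropriate
#'   mode (confidence threshold vs top fraction).
#' @param source_tag optional label; defaults to the dialect.
#' @return `umg_network`.
#' @export
read_edge_list <- function(path,
                           dialect = c("generic_tsv", "string_style",
                                       "humannet_style"),
                           source_tag = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty edge list file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  first <- 1L
  if (length(fields[[1]]) >= 3 && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    first <- 2L  # header row
    if (length(lines) < 2) stop("edge list file has a header but no data: ", path)
  }
  rows <- fields[first:length(fields)]
  bad <- which(vapply(rows, length, 1L) < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed edge list row at line %d of %s",
                 bad[1] + first - 1L, path))
  }
  w <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3L)))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop(sprintf("non-numeric score at line %d of %s", bad + first - 1L, path))
  }
  edges <- data.frame(from = vapply(rows, `[`, "", 1L),
                      to = vapply(rows, `[`, "", 2L),
                      weight = w, stringsAsFactors = FALSE)
  umg_network(edges, source_tag = source_tag %||% dialect)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter edges by confidence score
#'
#' Retains edges whose confidence is greater than or equal to `threshold`
#' (the boundary is inclusive). Isolated nodes are removed. Scores stored on
#' a 0-1000 integer scale (as distributed by some interaction databases) can
#' be handled by passing `scale_hint = 1000`, so a threshold of 0.7 keeps
#' combined scores >= 700.
#'
#' @param net `umg_network`.
#' @param threshold confidence threshold on the [0, 1] scale.
#' @param scale_hint divisor mapping stored scores onto [0, 1]; default 1
#'   (scores already on the threshold's scale).
#' @return Filtered `umg_network`.
#' @export
filter_by_confidence <- function(net, threshold, scale_hint = 1) {
  stopifnot(inherits(net, "umg_network"), is.numeric(threshold))
  w <- igraph::E(net$graph)$weight / scale_hint
  if (threshold > max(w) || threshold < min(w)) {
    warning(sprintf(
      "threshold %g is outside the observed score range [%g, %g]",
      threshold, min(w), max(w)))
  }
  keep <- which(w >= threshold)
  subgraph_from_edge_ids(net, keep)
}

#' Keep the top fraction of edges by weight
#'
#' Retains the `ceiling(fraction * |E|)` highest-weight edges; ties at the
#' cutoff weight are all retained, so the result may contain more edges than
#' the nominal count. Isolated nodes are removed.
#'
#' @param net `umg_network`.
#' @param fraction fraction of edges to keep, in (0, 1].
#' @return Filtered `umg_network`.
#' @export
filter_top_fraction <- function(net, fraction) {
  stopifnot(inherits(net, "umg_network"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  w <- igraph::E(net$graph)$weight
  if (length(w) == 0) stop("empty network")
  k <- ceiling(fraction * length(w))
  cutoff <- sort(w, decreasing = TRUE)[k]
  keep <- which(w >= cutoff)
  subgraph_from_edge_ids(net, keep)
}

subgraph_from_edge_ids <- function(net, edge_ids) {
  g <- igraph::subgraph_from_edges(net$graph, edge_ids, delete.vertices = TRUE)
  structure(list(graph = g, source_tag = net$source_tag),
            class = "umg_network")
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component. A tie on
#' component size is broken deterministically by the lexicographically
#' smallest member node.
#'
#' @param net `umg_network`.
#' @return `umg_network` restricted to the largest component.
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "umg_network"))
  if (network_size(net) == 0) stop("empty network")
  comp <- igraph::components(net$graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest lexicographic member decides
    reps <- vapply(best, function(ci) {
      min(igraph::V(net$graph)$name[comp$membership == ci])
    }, "")
    best <- best[order(reps)][1]
  }
  vids <- which(comp$membership == best)
  g <- igraph::induced_subgraph(net$graph, vids)
  structure(list(graph = g, source_tag = net$source_tag),
            class = "umg_network")
}

#' Remove nodes unexpressed in tumor samples
#'
#' Applies the expression rule: a gene is retained when its FPKM exceeds
#' `fpkm_threshold` in strictly more than `sample_fraction` of samples.
#' Genes absent from the expression matrix are removed. After node removal
#' the largest connected component is re-taken so the propagation substrate
#' stays connected; the component re-take is recorded in the result's
#' provenance attribute.
#'
#' @param net `umg_network`.
#' @param expr numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns; FPKM units, values >= 0.
#' @param fpkm_threshold FPKM cutoff (default 15).
#' @param sample_fraction fraction-of-samples cutoff in (0, 1); strict
#'   inequality (default 0.2).
#' @return Filtered `umg_network`.
#' @export
filter_by_expression <- function(net, expr, fpkm_threshold = 15,
                                 sample_fraction = 0.2) {
  stopifnot(inherits(net, "umg_network"), is.matrix(expr))
  if (ncol(expr) == 0) stop("expression matrix has zero samples")
  if (is.null(rownames(expr))) stop("expression matrix must have gene rownames")
  frac <- rowMeans(expr > fpkm_threshold)
  expressed <- rownames(expr)[frac > sample_fraction]
  keep <- intersect(igraph::V(net$graph)$name, expressed)
  if (length(keep) == 0) stop("no network gene passes the expression filter")
  g <- igraph::induced_subgraph(net$graph,
                                which(igraph::V(net$graph)$name %in% keep))
  # drop isolated nodes, then re-take the LCC
  deg <- igraph::degree(g)
  g <- igraph::induced_subgraph(g, which(deg > 0))
  if (igraph::vcount(g) == 0) stop("expression filter disconnected all edges")
  out <- structure(list(graph = g, source_tag = net$source_tag),
                   class = "umg_network")
  out <- largest_connected_component(out)
  attr(out, "lcc_retaken") <- TRUE
  out
}

#' Composite union of filtered networks
#'
#' Builds the node and edge union of two or more filtered networks. Edge
#' weights are first min-max rescaled to [0, 1] within each source network;
#' an edge present in several inputs keeps the maximum rescaled weight. The
#' composite network is intended for degree/adjacency queries (positionality
#' analysis), where the exact weights are immaterial.
#'
#' @param nets list of `umg_network` objects (length >= 2).
#' @return `umg_network` with `source_tag = "composite"`.
#' @export
composite_union <- function(nets) {
  stopifnot(is.list(nets), length(nets) >= 2)
  all_edges <- do.call(rbind, lapply(nets, function(n) {
    e <- network_edges(n)
    rng <- range(e$weight)
    e$weight <- if (rng[1] == rng[2]) rep(1, nrow(e)) else
      (e$weight - rng[1]) / (rng[2] - rng[1])
    # keep strictly positive weights after rescaling (min edge -> tiny eps)
    e$weight <- pmax(e$weight, 1e-6)
    e
  }))
  umg_network(all_edges, source_tag = "composite")
}

#' Write a network as a 3-column TSV edge list
#' @param net `umg_network`.
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(network_edges(net), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
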