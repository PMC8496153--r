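#' Stratify driver genes by initial score and composite-network degree
#'
#' Splits known driver genes into four classes by thresholding their initial
#' (pre-propagation) mutation score and their degree in the composite
#' network. Initial scores below `zero_floor` are zeroed first, which keeps
#' barely mutated drivers out of the high-score classes and lowers the false
#' positive rate of downstream categorization. Both thresholds are
#' inclusive (>=). Drivers absent from the composite network are excluded
#' and reported in the `missing` attribute.
#'
#' @param drivers character vector of driver gene identifiers.
#' @param IS named numeric vector of per-gene initial scores.
#' @param net composite `umg_network`.
#' @param score_threshold initial-score cutoff (default 0.075,
#'   quantized-score units).
#' @param degree_threshold degree cutoff (default 150, unweighted neighbor
#'   count).
#' @param zero_floor scores below this are zeroed (default 0.0015).
#' @return data.frame with columns `gene`, `IS`, `degree`, `class` where
#'   class is one of high_score_high_degree, high_score_low_degree,
#'   low_score_high_degree, low_score_low_degree.
#' @export
stratify_drivers <- function(drivers, IS, net, score_threshold = 0.075,
                             degree_threshold = 150, zero_floor = 0.0015) {
  stopifnot(inherits(net, "umg_network"), !is.null(names(IS)))
  nodes <- igraph::V(net$graph)$name
  missing <- setdiff(drivers, nodes)
  present <- intersect(drivers, nodes)
  is_val <- ifelse(drivers %in% names(IS), IS[drivers], 0)
  names(is_val) <- drivers
  is_val[is_val < zero_floor] <- 0
  deg <- igraph::degree(net$graph)[match(present, nodes)]
  hs <- is_val[present] >= score_threshold
  hd <- deg >= degree_threshold
  cls <- ifelse(hs & hd, "high_score_high_degree",
         ifelse(hs & !hd, "high_score_low_degree",
         ifelse(!hs & hd, "low_score_high_degree",
                "low_score_low_degree")))
  out <- data.frame(gene = present, IS = unname(is_val[present]),
                    degree = unname(deg), class = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  attr(out, "thresholds") <- c(score = score_threshold,
                               degree = degree_threshold,
                               zero_floor = zero_floor)
  out
}

#' Categorize upward-mobility genes by driver adjacency
#'
#' Labels each selected gene by its 1-hop relationship to stratified driver
#' genes in the composite network, applying the first matching rule:
#' \enumerate{
#'   \item own initial score below `zero_floor` (or the gene is absent from
#'     the composite network) -> `low_evidence`: the selection rests on
#'     nearly no observed mutations;
#'   \item neighbors include high-score drivers only -> `drug_target`: the
#'     gene sits in the immediate neighborhood of heavily mutated drivers
#'     and is a candidate synthetic-vulnerability target;
#'   \item neighbors include low-score drivers only -> `weak_driver`;
#'   \item neighbors include both kinds -> `both`;
#'   \item no driver neighbors but a positive own score -> `weak_driver`:
#'     mutation signal of its own, not explained by driver adjacency.
#' }
#'
#' @param umgs character vector of selected gene identifiers.
#' @param strat driver stratification from [stratify_drivers()].
#' @param IS named numeric vector of per-gene initial scores.
#' @param net composite `umg_network`.
#' @param zero_floor score floor, matching [stratify_drivers()]
#'   (default 0.0015).
#' @return data.frame with columns `gene`, `label`, `IS`, `degree`,
#'   `n_high_score_drivers`, `n_low_score_drivers`, `in_network`.
#' @export
categorize_umgs <- function(umgs, strat, IS, net, zero_floor = 0.0015) {
  stopifnot(inherits(net, "umg_network"), is.data.frame(strat))
  nodes <- igraph::V(net$graph)$name
  high <- strat$gene[startsWith(strat$class, "high_score")]
  low <- strat$gene[startsWith(strat$class, "low_score")]
  res <- lapply(umgs, function(g) {
    own <- if (g %in% names(IS)) unname(IS[g]) else 0
    if (!g %in% nodes) {
      return(data.frame(gene = g, label = "low_evidence", IS = own,
                        degree = NA_integer_, n_high_score_drivers = 0L,
                        n_low_score_drivers = 0L, in_network = FALSE,
                        stringsAsFactors = FALSE))
    }
    nb <- igraph::V(net$graph)$name[
      as.integer(igraph::neighbors(net$graph, g))]
    nh <- length(intersect(nb, high))
    nl <- length(intersect(nb, low))
    label <- if (own < zero_floor) "low_evidence"
      else if (nh > 0 && nl == 0) "drug_target"
      else if (nl > 0 && nh == 0) "weak_driver"
      else if (nh > 0 && nl > 0) "both"
      else "weak_driver"
    data.frame(gene = g, label = label, IS = own,
               degree = length(nb), n_high_score_drivers = nh,
               n_low_score_drivers = nl, in_network = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export the UMG-driver subgraph as an edge list
#'
#' Extracts the edges between selected genes and driver genes in the
#' composite network (1-hop, the edges the categorization is based on) for
#' external visualization.
#'
#' @param umgs character vector of selected genes.
#' @param drivers character vector of driver genes.
#' @param net composite `umg_network`.
#' @return data.frame `from` (UMG), `to` (driver), `weight`.
#' @export
umg_driver_edges <- function(umgs, drivers, net) {
  e <- network_edges(net)
  keep <- (e$from %in% umgs & e$to %in% drivers) |
    (e$to %in% umgs & e$from %in% drivers)
  sub <- e[keep, , drop = FALSE]
  flip <- sub$to %in% umgs & !(sub$from %in% umgs)
  tmp <- sub$from[flip]
  sub$from[flip] <- sub$to[flip]
  sub$to[flip] <- tmp
  rownames(sub) <- NULL
  sub
}
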