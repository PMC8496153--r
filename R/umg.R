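#' Per-gene mean initial and final scores
#'
#' The initial score IS of a gene is the arithmetic average of its seed
#' scores across samples; the final score FS is the same average on the
#' propagated scores.
#'
#' @param S0 gene x sample seed matrix.
#' @param Sfinal gene x sample propagated matrix, same shape and gene order.
#' @return data.frame with columns `gene`, `IS`, `FS`.
#' @export
mean_scores <- function(S0, Sfinal) {
  stopifnot(is.matrix(S0), is.matrix(Sfinal),
            all(dim(S0) == dim(Sfinal)),
            identical(rownames(S0), rownames(Sfinal)))
  if (ncol(S0) == 0) stop("zero samples: mean scores undefined")
  data.frame(gene = rownames(S0),
             IS = rowMeans(S0),
             FS = rowMeans(Sfinal),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes by score (1 = highest score)
#'
#' Higher scores get better (lower-valued) ranks. Tied scores share the
#' average of the rank positions they span, which is deterministic and
#' independent of input order; this matters because long-tail cohorts have
#' large blocks of zero-score genes. An ordinal first-seen mode is
#' available.
#'
#' @param scores numeric vector (optionally named).
#' @param ties "average" (default) or "first".
#' @return Numeric vector of ranks, same length and names as `scores`.
#' @export
rank_scores <- function(scores, ties = c("average", "first")) {
  ties <- match.arg(ties)
  if (!all(is.finite(scores))) stop("scores must be finite")
  rank(-scores, ties.method = ties)
}

#' Mobility status: initial rank minus final rank
#'
#' Positive values indicate upward mobility (the gene's rank improved during
#' propagation), negative values downward mobility.
#'
#' @param RIS initial ranks.
#' @param RFS final ranks, same gene universe and order.
#' @return Numeric vector MS = RIS - RFS.
#' @export
mobility <- function(RIS, RFS) {
  stopifnot(length(RIS) == length(RFS))
  RIS - RFS
}

#' Full per-gene ranking table
#'
#' Combines mean scores, tie-aware ranks before and after propagation, and
#' mobility status into the per-network ranking table.
#'
#' @inheritParams mean_scores
#' @param ties tie policy passed to [rank_scores()].
#' @return data.frame with columns `gene`, `IS`, `FS`, `RIS`, `RFS`, `MS`.
#' @export
gene_ranking <- function(S0, Sfinal, ties = "average") {
  ms <- mean_scores(S0, Sfinal)
  ms$RIS <- rank_scores(ms$IS, ties)
  ms$RFS <- rank_scores(ms$FS, ties)
  ms$MS <- mobility(ms$RIS, ms$RFS)
  ms
}

#' Cohort-specific default mobility thresholds
#'
#' The mobility parameter beta scales with cohort size and the variance of
#' the cohort's gene mutation frequency: large and/or high-variance cohorts
#' demand bigger upward jumps.
#'
#' @format Named numeric vector, TCGA cohort label -> beta.
#' @export
umg_beta_defaults <- c(
  BRCA = 0.25, COAD = 0.25, HNSC = 0.25, LUAD = 0.25, LUSC = 0.25,
  PRAD = 0.25, STAD = 0.25, UCEC = 0.25,
  CESC = 0.20, KIRC = 0.20, KIRP = 0.20, LIHC = 0.20,
  ESCA = 0.15, READ = 0.15,
  CHOL = 0.05, KICH = 0.05, THCA = 0.05
)

#' Default beta for a cohort label
#'
#' @param cohort cohort label (e.g. "BRCA").
#' @return beta value; errors for unknown cohorts (supply beta explicitly).
#' @export
default_beta <- function(cohort) {
  if (!cohort %in% names(umg_beta_defaults)) {
    stop("no default beta for cohort '", cohort,
         "'; supply beta explicitly")
  }
  unname(umg_beta_defaults[cohort])
}

#' Select upward-mobility genes
#'
#' A gene is an upward-mobility gene when its rank improves by at least
#' beta * |G| positions (MS >= beta * |G|, compared in reals, boundary
#' inclusive) and its post-propagation rank is within the top T
#' (RFS <= T, inclusive). Frequently mutated genes already at the top
#' cannot make the required jump, so the rule structurally excludes known
#' drivers.
#'
#' @param ranking data.frame from [gene_ranking()].
#' @param beta mobility fraction in (0, 1).
#' @param rank_threshold top-rank cutoff T (default 1000).
#' @param G_size size of the gene universe |G|; defaults to `nrow(ranking)`.
#' @return data.frame of selected rows, ordered by RFS ascending.
#' @export
select_umgs <- function(ranking, beta, rank_threshold = 1000,
                        G_size = nrow(ranking)) {
  stopifnot(is.data.frame(ranking),
            all(c("gene", "RIS", "RFS", "MS") %in% names(ranking)))
  if (!is.numeric(beta) || beta <= 0 || beta >= 1) {
    stop("beta must be in (0, 1)")
  }
  sel <- ranking[ranking$MS >= beta * G_size &
                   ranking$RFS <= rank_threshold, , drop = FALSE]
  sel <- sel[order(sel$RFS, sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Cell-line dependency data container
#'
#' Bundles one gene x cell-line effect-score matrix per assay (typically
#' CRISPR knockout and RNAi) with a cell-line -> cancer-type annotation.
#' Negative effect scores mean gene knockout impaired viability; 0 means no
#' effect.
#'
#' @param assays named list of numeric matrices (genes in rows, cell lines
#'   in columns, both named).
#' @param annotation data.frame with columns `cell_line`, `cancer_type`.
#' @return Object of class `dependency_data`.
#' @export
dependency_data <- function(assays, annotation) {
  stopifnot(is.list(assays), length(assays) >= 1,
            !is.null(names(assays)), !any(duplicated(names(assays))))
  for (nm in names(assays)) {
    m <- assays[[nm]]
    stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
    if (any(duplicated(colnames(m)))) {
      stop("duplicate cell lines in assay ", nm)
    }
  }
  stopifnot(is.data.frame(annotation),
            all(c("cell_line", "cancer_type") %in% names(annotation)))
  structure(list(assays = assays, annotation = annotation),
            class = "dependency_data")
}

#' @export
print.dependency_data <- function(x, ...) {
  for (nm in names(x$assays)) {
    cat(sprintf("assay %s: %d genes x %d cell lines\n", nm,
                nrow(x$assays[[nm]]), ncol(x$assays[[nm]])))
  }
  invisible(x)
}

#' Read a dependency matrix CSV
#'
#' Reads a genes x cell-lines CSV as distributed by dependency-screen
#' portals. The gene field may be "SYMBOL (ENTREZ)"; the symbol is extracted
#' by splitting at the first space or parenthesis.
#'
#' @param path CSV file path; first column gene, remaining columns cell
#'   lines.
#' @return Numeric matrix with gene symbols as rownames.
#' @export
read_dependency_matrix <- function(path) {
  if (!file.exists(path)) stop("dependency matrix not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- sub("[ (].*$", "", as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

cancer_type_lines <- function(mat, dep, cancer_type) {
  ann <- dep$annotation
  lines <- ann$cell_line[ann$cancer_type == cancer_type]
  lines <- intersect(colnames(mat), lines)
  if (length(lines) == 0) {
    # cancer type unrepresented among annotated lines: fall back to all
    lines <- colnames(mat)
  }
  lines
}

#' Filter genes by cell-line dependency evidence
#'
#' For each assay, a gene's dependency fraction is the proportion of the
#' cancer type's cell lines in which its effect score is strictly negative
#' (knockout impaired viability). DM is the maximum fraction across assays;
#' a gene is kept when DM >= p. Cancer types with no annotated cell lines
#' fall back to all cell lines in the assay. Genes absent from every assay
#' carry no dependency evidence and pass the (optional) filter with a flag.
#'
#' @param genes character vector of gene identifiers.
#' @param dep `dependency_data`.
#' @param cancer_type cancer-type label matching the annotation.
#' @param p minimum dependency fraction (default 0.5).
#' @return data.frame with columns `gene`, `DM`, `kept`, `no_data`;
#'   per-assay fractions as extra columns `DM_<assay>`.
#' @export
depmap_filter <- function(genes, dep, cancer_type, p = 0.5) {
  stopifnot(inherits(dep, "dependency_data"))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  per_assay <- matrix(NA_real_, length(genes), length(dep$assays),
                      dimnames = list(genes, names(dep$assays)))
  for (nm in names(dep$assays)) {
    mat <- dep$assays[[nm]]
    lines <- cancer_type_lines(mat, dep, cancer_type)
    if (length(lines) == 0) next  # assay with zero usable lines is skipped
    present <- intersect(genes, rownames(mat))
    if (length(present) > 0) {
      per_assay[present, nm] <-
        rowMeans(mat[present, lines, drop = FALSE] < 0)
    }
  }
  dm <- apply(per_assay, 1, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  out$DM <- unname(dm)
  out$no_data <- is.na(dm)
  out$kept <- out$no_data | (!is.na(dm) & dm >= p)
  for (nm in colnames(per_assay)) out[[paste0("DM_", nm)]] <- per_assay[, nm]
  rownames(out) <- NULL
  out
}

#' Intersect per-network UMG lists
#'
#' The final gene list is the set intersection of the per-network
#' selections, ordered by the mean post-propagation rank (RFS) across
#' networks. A warning is emitted when the intersection is empty.
#'
#' @param per_network list (length >= 1) of data.frames with columns `gene`
#'   and `RFS` (e.g. outputs of [select_umgs()]), or plain character
#'   vectors (then ordering falls back to alphabetical).
#' @return data.frame with columns `gene` and `mean_RFS`, ordered by
#'   `mean_RFS` ascending.
#' @export
intersect_networks <- function(per_network) {
  stopifnot(is.list(per_network), length(per_network) >= 1)
  lists <- lapply(per_network, function(x) {
    if (is.character(x)) data.frame(gene = x, RFS = NA_real_,
                                    stringsAsFactors = FALSE)
    else x[, c("gene", "RFS")]
  })
  common <- Reduce(intersect, lapply(lists, `[[`, "gene"))
  if (length(common) == 0) {
    warning("empty intersection across networks")
    return(data.frame(gene = character(), mean_RFS = numeric(),
                      stringsAsFactors = FALSE))
  }
  rfs <- vapply(common, function(g) {
    mean(vapply(lists, function(l) l$RFS[match(g, l$gene)], 0))
  }, 0)
  out <- data.frame(gene = common, mean_RFS = unname(rfs),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_RFS, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
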