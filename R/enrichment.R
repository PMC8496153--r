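# Mann-Whitney U machinery. U counts pairs (x, y) with x < y (plus half
# ties), i.e. large U means x-values are smaller. Exact p by enumeration of
# group assignments for small samples; tie-corrected normal approximation
# with continuity correction otherwise.

mw_u_statistic <- function(x, y) {
  # U for "x smaller than y": n1*n2 - (R_x - n1(n1+1)/2) on midranks
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(n1)])
  n1 * n2 + n1 * (n1 + 1) / 2 - rx
}

mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- mw_u_statistic(x, y)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) {
    mw_u_statistic(pooled[i], pooled[-i])
  })
  mean(us >= u_obs - 1e-9)
}

mw_normal_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  u <- mw_u_statistic(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(0.5)  # everything tied: no evidence either way
  z <- (u - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' One-sided Mann-Whitney test that one group's values are smaller
#'
#' Tests H1: values in `x` are stochastically smaller than values in `y`
#' (alternative "less"), or larger ("greater"). Uses exact enumeration of
#' all group assignments when the pooled size is at most `exact_limit`, and
#' the tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y numeric vectors.
#' @param alternative "less" (x smaller) or "greater" (x larger).
#' @param exact_limit pooled-size cutoff for exact enumeration (default 12).
#' @return list with `U` (statistic for the stated alternative), `p_value`,
#'   `n_x`, `n_y`, `method` ("exact" or "normal_approx").
#' @export
mann_whitney <- function(x, y, alternative = c("less", "greater"),
                         exact_limit = 12) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (!all(is.finite(c(x, y)))) stop("values must be finite")
  if (alternative == "greater") {
    tmp <- x; x <- -x; y <- -y  # larger x  <=>  smaller -x
  }
  exact <- (length(x) + length(y)) <= exact_limit
  p <- if (exact) mw_exact_p(x, y) else mw_normal_p(x, y)
  list(U = mw_u_statistic(x, y), p_value = p,
       n_x = length(x), n_y = length(y),
       method = if (exact) "exact" else "normal_approx")
}

#' Enrichment of a reference gene set toward top ranks
#'
#' One-sided Mann-Whitney test that reference genes (e.g. the COSMIC cancer
#' gene census, or cohort driver genes) occupy better ranks - lower rank
#' values - than the remaining genes. Used to validate that propagation
#' pushes known cancer genes toward the top of the ranking.
#'
#' @param ranks named numeric vector of per-gene ranks (1 = best).
#' @param reference character vector of reference gene identifiers.
#' @return list of class `enrichment_result` with `U`, `p_value`,
#'   `n_reference`, `n_other`, `direction`, `method`.
#' @export
rank_enrichment <- function(ranks, reference) {
  if (is.null(names(ranks))) stop("ranks must be named by gene")
  ref <- intersect(names(ranks), reference)
  oth <- setdiff(names(ranks), reference)
  if (length(ref) == 0) stop("no reference gene present in the ranking")
  if (length(oth) == 0) stop("no non-reference gene present in the ranking")
  res <- mann_whitney(ranks[ref], ranks[oth], alternative = "less")
  structure(list(U = res$U, p_value = res$p_value,
                 n_reference = length(ref), n_other = length(oth),
                 direction = "reference ranked higher",
                 method = res$method),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("one-sided rank-sum enrichment (%s): U = %g, p = %.4g (n = %d vs %d)\n",
              x$method, x$U, x$p_value, x$n_reference, x$n_other))
  invisible(x)
}

#' Percentage-based cell-line impact score
#'
#' For a gene with dependency scores over k cancer-type-specific cell lines,
#' let b_j = 1 when the score in line j is strictly negative (knockout
#' impaired viability) and 0 otherwise. The impact score is
#' psi = (sum(b_j) + mean(b_j)) / (k + 2): the k binary indicators plus
#' their mean, smoothed by a k + 2 denominator that behaves as if at least
#' one line with a non-negative score were always present. Hence
#' 0 <= psi < 1 strictly, and psi is monotone in the number of negative
#' lines. Cancer types with no annotated cell lines fall back to all lines
#' in the assay.
#'
#' The plain negative fraction sum(b_j)/k (the DM quantity used by
#' [depmap_filter()]) is available via `variant = "fraction"`.
#'
#' @param genes character vector of gene identifiers.
#' @param dep `dependency_data`.
#' @param cancer_type cancer-type label.
#' @param assay assay name within `dep` (e.g. "CRISPR").
#' @param variant "smoothed" (default) or "fraction".
#' @return data.frame with columns `gene`, `psi`, `k`, `n_negative`;
#'   genes absent from the assay get NA psi.
#' @export
impact_score <- function(genes, dep, cancer_type, assay,
                         variant = c("smoothed", "fraction")) {
  variant <- match.arg(variant)
  stopifnot(inherits(dep, "dependency_data"))
  if (!assay %in% names(dep$assays)) stop("unknown assay: ", assay)
  mat <- dep$assays[[assay]]
  lines <- cancer_type_lines(mat, dep, cancer_type)
  if (length(lines) == 0) stop("assay has no usable cell lines")
  k <- length(lines)
  out <- data.frame(gene = genes, psi = NA_real_, k = k,
                    n_negative = NA_integer_, stringsAsFactors = FALSE)
  present <- intersect(genes, rownames(mat))
  if (length(present) > 0) {
    b <- mat[present, lines, drop = FALSE] < 0
    nneg <- rowSums(b)
    psi <- if (variant == "smoothed") (nneg + nneg / k) / (k + 2) else nneg / k
    out$psi[match(present, out$gene)] <- psi
    out$n_negative[match(present, out$gene)] <- as.integer(nneg)
  }
  out
}

#' Compare impact-score distributions between gene groups
#'
#' One-sided Mann-Whitney test that the impact scores of one group (the
#' selected upward-mobility genes) are shifted to the right of (larger
#' than) a background group's, i.e. that their knockouts impair cell-line
#' viability more often.
#'
#' @param umg character vector of selected genes.
#' @param background character vector of background genes.
#' @inheritParams impact_score
#' @return list of class `enrichment_result` (direction: umg shifted right).
#' @export
compare_groups <- function(umg, background, dep, cancer_type, assay,
                           variant = "smoothed") {
  psi_u <- impact_score(umg, dep, cancer_type, assay, variant)$psi
  psi_b <- impact_score(background, dep, cancer_type, assay, variant)$psi
  psi_u <- psi_u[!is.na(psi_u)]
  psi_b <- psi_b[!is.na(psi_b)]
  if (length(psi_u) == 0 || length(psi_b) == 0) {
    stop("a group has no gene with dependency data")
  }
  res <- mann_whitney(psi_u, psi_b, alternative = "greater")
  structure(list(U = res$U, p_value = res$p_value,
                 n_reference = length(psi_u), n_other = length(psi_b),
                 direction = "umg impact shifted right",
                 method = res$method),
            class = "enrichment_result")
}

#' Read a plain-text gene set
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return Character vector of gene identifiers.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}
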