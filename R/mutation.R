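#' Gene-by-sample somatic mutation count matrix
#'
#' Tabulates retained variants into a gene x sample count matrix. Variants
#' whose class is not in `keep_classes` are excluded; the canonical default
#' restricts to splicing and coding exonic variants, the classes that alter
#' the transcribed protein product.
#'
#' @param variants data.frame with columns `sample_id`, `gene`,
#'   `variant_class` (extra columns ignored).
#' @param keep_classes character vector of variant classes to retain.
#' @return Integer matrix, genes in rows (sorted), samples in columns
#'   (sorted); entry (g, s) is the number of retained variants of gene g in
#'   sample s. All genes and samples observed in `variants` appear, even if
#'   all their retained counts are zero.
#' @export
count_matrix <- function(variants, keep_classes = c("exonic", "splicing")) {
  stopifnot(is.data.frame(variants),
            all(c("sample_id", "gene", "variant_class") %in% names(variants)))
  if (length(keep_classes) == 0) stop("keep_classes must be non-empty")
  genes <- sort(unique(as.character(variants$gene)))
  samples <- sort(unique(as.character(variants$sample_id)))
  kept <- variants[variants$variant_class %in% keep_classes, , drop = FALSE]
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(kept) > 0) {
    tab <- table(factor(kept$gene, levels = genes),
                 factor(kept$sample_id, levels = samples))
    m[] <- as.integer(tab)
  }
  m
}

#' Normalize mutation counts by gene length
#'
#' Divides each gene's counts by its coding length in base pairs, yielding
#' mutation frequencies in counts per bp. Every counted gene must have a
#' length.
#'
#' @param counts gene x sample count matrix (rownames = genes).
#' @param lengths named numeric vector or two-column data.frame
#'   (gene, length) of positive gene lengths in bp.
#' @return Numeric matrix of the same shape, counts per bp.
#' @export
length_normalize <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(as.numeric(lengths[[2]]),
                               as.character(lengths[[1]]))
  }
  if (any(duplicated(names(lengths)))) stop("duplicate genes in length table")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0) {
    stop("genes missing from the length table: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  counts / lengths[rownames(counts)]
}

#' Quantize normalized mutation frequencies into scores 1-4
#'
#' Pools all non-zero normalized frequencies and computes their 50th, 70th
#' and 90th percentiles (linear interpolation between order statistics,
#' `quantile` type 7). Each non-zero value v is mapped by its position in
#' that distribution: v <= p50 -> 1, p50 < v <= p70 -> 2, p70 < v <= p90 ->
#' 3, v > p90 -> 4. Zeros stay 0. The mapping is monotone by construction.
#'
#' @param norm normalized gene x sample frequency matrix.
#' @param dialect "pooled" (default) computes percentiles over all non-zero
#'   matrix entries; "per_gene" computes them over per-gene mean non-zero
#'   frequencies (alternate reading of the cohort frequency distribution).
#' @return list with `matrix` (integer matrix of scores in 0..4) and
#'   `thresholds` (named vector p50, p70, p90, counts-per-bp units).
#' @export
quantize <- function(norm, dialect = c("pooled", "per_gene")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(norm))
  if (any(norm < 0)) stop("normalized frequencies must be non-negative")
  nz <- norm[norm > 0]
  if (length(nz) == 0) stop("all-zero mutation matrix: nothing to quantize")
  pool <- if (dialect == "pooled") nz else {
    means <- apply(norm, 1, function(r) if (any(r > 0)) mean(r[r > 0]) else 0)
    means[means > 0]
  }
  q <- stats::quantile(pool, c(0.5, 0.7, 0.9), type = 7, names = FALSE)
  lvl <- matrix(0L, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  pos <- norm > 0
  v <- norm[pos]
  lvl[pos] <- 1L + (v > q[1]) + (v > q[2]) + (v > q[3])
  list(matrix = lvl,
       thresholds = c(p50 = q[1], p70 = q[2], p90 = q[3]))
}

#' Read a MAF-like variant table
#'
#' Reads a TSV of somatic variants with configurable column names, returning
#' the normalized three-column layout used by [count_matrix()].
#'
#' @param path TSV file path (header required).
#' @param columns named list mapping `sample`, `gene`, `class` to the column
#'   names in the file.
#' @return data.frame with columns `sample_id`, `gene`, `variant_class`.
#' @export
read_variants <- function(path,
                          columns = list(sample = "sample_id", gene = "gene",
                                         class = "variant_class")) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(columns[c("sample", "gene", "class")])
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("variant table lacks columns: ",
                             paste(miss, collapse = ", "))
  data.frame(sample_id = as.character(tab[[columns$sample]]),
             gene = as.character(tab[[columns$gene]]),
             variant_class = as.character(tab[[columns$class]]),
             stringsAsFactors = FALSE)
}

#' Build the quantized mutation matrix from variants
#'
#' Convenience wrapper chaining [count_matrix()], [length_normalize()] and
#' [quantize()].
#'
#' @inheritParams count_matrix
#' @inheritParams length_normalize
#' @inheritParams quantize
#' @return list with `scores` (quantized matrix), `thresholds`, `counts`
#'   and `normalized` matrices.
#' @export
build_mutation_matrix <- function(variants, lengths,
                                  keep_classes = c("exonic", "splicing"),
                                  dialect = "pooled") {
  counts <- count_matrix(variants, keep_classes)
  norm <- length_normalize(counts, lengths)
  qz <- quantize(norm, dialect)
  list(scores = qz$matrix, thresholds = qz$thresholds,
       counts = counts, normalized = norm)
}
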