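#' Synthetic cohort specification
#'
#' Parameters of the seeded synthetic cohort generator. The defaults emulate
#' the statistical structure the prioritization method exploits: a
#' hub-dominated (scale-free) interaction network, a long-tail mutation
#' frequency distribution, a handful of heavily mutated driver hubs, and a
#' small set of rarely mutated genes wired into those mutated
#' neighborhoods - the planted upward-mobility truth set.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_samples cohort size (default 100).
#' @param attachment preferential-attachment parameter m: edges added per
#'   new node during graph growth (default 3).
#' @param n_planted_drivers hub genes with high mutation rates (default 10).
#' @param n_planted_umgs rarely mutated genes wired to drivers (default 15).
#' @param background_rate base per-sample mutation probability of background
#'   genes; per-gene rates get a Pareto-shaped multiplier so the cohort
#'   marginal is heavy-tailed (default 0.004).
#' @param driver_rate per-sample mutation probability of planted drivers
#'   (default 0.45).
#' @param umg_driver_links edges from each planted gene to distinct drivers,
#'   shared across both generated networks (default 4).
#' @param neighborhood_boost lower bound of the planted-edge weight
#'   distribution: planted genes interact with their driver neighborhood at
#'   high confidence, so those edges draw weights from
#'   uniform(`neighborhood_boost`, 1] instead of the background
#'   uniform(0.5, 1] (default 0.9).
#' @param planted_neg_rate probability a planted gene's dependency score is
#'   negative in a cell line (default 0.9).
#' @param background_neg_rate same for background genes (default 0.3).
#' @param n_cell_lines cell lines in the CRISPR assay; the RNAi assay gets
#'   3/4 of this (default 24).
#' @param unexpressed_fraction fraction of background genes generated as
#'   unexpressed, to exercise the FPKM filter (default 0.05).
#' @param seed mandatory RNG seed.
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_genes = 2000, n_samples = 100,
                                  attachment = 3, n_planted_drivers = 10,
                                  n_planted_umgs = 15,
                                  background_rate = 0.005,
                                  driver_rate = 0.5,
                                  umg_driver_links = 4,
                                  neighborhood_boost = 0.9,
                                  planted_neg_rate = 0.9,
                                  background_neg_rate = 0.3,
                                  n_cell_lines = 24,
                                  unexpressed_fraction = 0.05,
                                  seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_planted_drivers + n_planted_umgs > n_genes) {
    stop("planted gene counts exceed n_genes")
  }
  if (any(c(background_rate, driver_rate, planted_neg_rate,
            background_neg_rate, unexpressed_fraction) < 0) ||
      any(c(background_rate, driver_rate, planted_neg_rate,
            background_neg_rate, unexpressed_fraction) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  if (umg_driver_links > n_planted_drivers) {
    stop("umg_driver_links cannot exceed n_planted_drivers")
  }
  if (neighborhood_boost < 0.5 || neighborhood_boost >= 1) {
    stop("neighborhood_boost must lie in [0.5, 1)")
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 attachment = attachment,
                 n_planted_drivers = n_planted_drivers,
                 n_planted_umgs = n_planted_umgs,
                 background_rate = background_rate,
                 driver_rate = driver_rate,
                 umg_driver_links = umg_driver_links,
                 neighborhood_boost = neighborhood_boost,
                 planted_neg_rate = planted_neg_rate,
                 background_neg_rate = background_neg_rate,
                 n_cell_lines = n_cell_lines,
                 unexpressed_fraction = unexpressed_fraction,
                 seed = seed),
            class = "synthetic_cohort_spec")
}

# one preferential-attachment network whose hubs carry the driver names,
# with the shared planted UMG-driver edges added on top
synth_network <- function(spec, genes, drivers, planted, planted_edges, tag) {
  g <- igraph::sample_pa(spec$n_genes, m = spec$attachment, directed = FALSE)
  deg <- igraph::degree(g)
  ord <- order(deg, decreasing = TRUE)
  labels <- character(spec$n_genes)
  labels[ord[seq_len(spec$n_planted_drivers)]] <- sample(drivers)
  rest <- setdiff(genes, drivers)
  labels[ord[-seq_len(spec$n_planted_drivers)]] <-
    sample(rest, length(rest))
  igraph::V(g)$name <- labels
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = stats::runif(nrow(el), 0.5, 1),
                      stringsAsFactors = FALSE)
  edges <- rbind(edges, planted_edges)
  umg_network(edges, source_tag = tag)
}

#' Generate a seeded synthetic cohort with planted structure
#'
#' Produces every input the pipeline consumes: two overlapping scale-free
#' networks (distinct random growths that share the planted driver-UMG
#' edges, so cross-network intersection is exercised), a somatic variant
#' table with a heavy-tailed per-gene mutation marginal, a gene-length
#' table, an FPKM expression matrix in which all planted genes pass the
#' expression filter, dependency matrices (CRISPR and RNAi assays) in which
#' planted genes score negative at a high rate, the driver set, and the
#' planted truth set. Fully deterministic given `spec$seed`.
#'
#' Planted drivers are mapped onto the network hubs and mutated in a large
#' fraction of samples; planted upward-mobility genes carry background-level
#' mutation counts (at least one mutation is guaranteed, as a gene with no
#' mutations at all carries no signal to rank) but hold edges to several
#' distinct driver hubs in both networks.
#'
#' @param spec `synthetic_cohort_spec`.
#' @return list with elements `networks` (list of two `umg_network`),
#'   `variants`, `gene_lengths`, `expression`, `dependency`
#'   (`dependency_data`), `drivers`, `planted_umgs`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  drivers <- sort(sample(genes, spec$n_planted_drivers))
  planted <- sort(sample(setdiff(genes, drivers), spec$n_planted_umgs))

  # shared planted subgraph: each planted gene holds high-confidence edges
  # to several distinct drivers
  planted_edges <- do.call(rbind, lapply(planted, function(u) {
    tgt <- sample(drivers, spec$umg_driver_links)
    data.frame(from = u, to = tgt,
               weight = stats::runif(length(tgt),
                                     spec$neighborhood_boost, 1),
               stringsAsFactors = FALSE)
  }))

  networks <- list(
    synth_network(spec, genes, drivers, planted, planted_edges, "synth_net1"),
    synth_network(spec, genes, drivers, planted, planted_edges, "synth_net2"))

  # per-gene per-sample mutation probability: Pareto-tailed background so
  # the cohort marginal over genes is heavy-tailed (many genes with one or
  # two mutations, a few background genes with dozens)
  u <- stats::runif(spec$n_genes)
  rate <- pmin(spec$background_rate * u^(-0.7), 0.25)
  names(rate) <- genes
  rate[drivers] <- spec$driver_rate
  rate[planted] <- 0  # planted mutations are drawn separately below

  classes <- c("exonic", "splicing", "intronic", "synonymous")
  vl <- list()
  for (g in genes) {
    if (g %in% planted) {
      # minimal long-tail signal: a single exonic variant in one sample
      s <- sample.int(spec$n_samples, 1)
      vl[[length(vl) + 1L]] <- data.frame(
        sample_id = samples[s], gene = g, variant_class = "exonic",
        stringsAsFactors = FALSE)
      next
    }
    hit <- which(stats::runif(spec$n_samples) < rate[g])
    for (s in hit) {
      # drivers accumulate several distinct variants in a mutated sample
      n_var <- 1L + stats::rpois(1, if (g %in% drivers) 1.2 else 0.3)
      cls <- sample(classes, n_var, replace = TRUE,
                    prob = c(0.6, 0.1, 0.2, 0.1))
      vl[[length(vl) + 1L]] <- data.frame(
        sample_id = samples[s], gene = g, variant_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, vl)
  rownames(variants) <- NULL

  gene_lengths <- stats::setNames(
    pmax(200, round(stats::rlnorm(spec$n_genes, log(2500), 0.6))), genes)
  # planted genes are archetypal long-tail genes: large proteins whose
  # single mutation yields a minimal length-normalized frequency, placing
  # them at the bottom of the non-zero score distribution
  gene_lengths[planted] <- round(stats::runif(
    spec$n_planted_umgs, 2, 4) * exp(log(2500) + 0.6))

  # expression: planted genes and drivers always pass FPKM > 15 in > 20%
  n_unexpr <- round(spec$unexpressed_fraction * spec$n_genes)
  unexpressed <- sample(setdiff(genes, c(drivers, planted)), n_unexpr)
  base <- stats::runif(spec$n_genes, 20, 100)
  names(base) <- genes
  base[unexpressed] <- stats::runif(n_unexpr, 0, 8)
  base[c(drivers, planted)] <- stats::runif(
    length(c(drivers, planted)), 40, 100)
  expression <- matrix(
    base * stats::runif(spec$n_genes * spec$n_samples, 0.8, 1.2),
    spec$n_genes, spec$n_samples, dimnames = list(genes, samples))

  dependency <- synth_dependency(spec, genes, drivers, planted)

  list(networks = networks, variants = variants,
       gene_lengths = gene_lengths, expression = expression,
       dependency = dependency, drivers = drivers,
       planted_umgs = planted, spec = spec)
}

synth_dependency <- function(spec, genes, drivers, planted) {
  neg_rate <- stats::setNames(rep(spec$background_neg_rate, length(genes)),
                              genes)
  neg_rate[c(drivers, planted)] <- spec$planted_neg_rate
  make_assay <- function(n_lines, prefix) {
    lines <- sprintf("%s%02d", prefix, seq_len(n_lines))
    neg <- matrix(stats::runif(length(genes) * n_lines) <
                    neg_rate[genes], length(genes), n_lines)
    m <- matrix(stats::rnorm(length(genes) * n_lines, 0.1, 0.08),
                length(genes), n_lines, dimnames = list(genes, lines))
    m[neg] <- stats::rnorm(sum(neg), -0.6, 0.2)
    m[neg & m >= 0] <- -0.1
    m[!neg & m < 0] <- 0.05
    m
  }
  crispr <- make_assay(spec$n_cell_lines, "CLC")
  rnai <- make_assay(max(2, round(spec$n_cell_lines * 0.75)), "CLR")
  ann <- data.frame(
    cell_line = c(colnames(crispr), colnames(rnai)),
    cancer_type = "SYNTH", stringsAsFactors = FALSE)
  # leave a few lines annotated to a different type to exercise selection
  ann$cancer_type[seq_len(min(3, nrow(ann)))] <- "OTHER"
  dependency_data(assays = list(CRISPR = crispr, RNAi = rnai),
                  annotation = ann)
}

#' Write a synthetic cohort to standard-format files
#'
#' Emits the cohort as the plain-text formats the pipeline reads: edge-list
#' TSVs, a variant TSV, a gene-length TSV, an expression TSV, dependency
#' CSVs, an annotation TSV and the driver / planted-gene text sets.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  for (i in seq_along(cohort$networks)) {
    p[[paste0("network", i)]] <- file.path(dir, sprintf("network%d.tsv", i))
    write_edge_list(cohort$networks[[i]], p[[paste0("network", i)]])
  }
  p$variants <- file.path(dir, "variants.tsv")
  utils::write.table(cohort$variants, p$variants, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p$gene_lengths <- file.path(dir, "gene_lengths.tsv")
  utils::write.table(
    data.frame(gene = names(cohort$gene_lengths),
               length = unname(cohort$gene_lengths)),
    p$gene_lengths, sep = "\t", quote = FALSE, row.names = FALSE)
  p$expression <- file.path(dir, "expression.tsv")
  utils::write.table(
    data.frame(gene = rownames(cohort$expression), cohort$expression,
               check.names = FALSE),
    p$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(cohort$dependency$assays)) {
    key <- paste0("dependency_", tolower(nm))
    p[[key]] <- file.path(dir, paste0(key, ".csv"))
    utils::write.csv(
      data.frame(gene = rownames(cohort$dependency$assays[[nm]]),
                 cohort$dependency$assays[[nm]], check.names = FALSE),
      p[[key]], row.names = FALSE, quote = FALSE)
  }
  p$annotation <- file.path(dir, "cell_line_annotation.tsv")
  utils::write.table(cohort$dependency$annotation, p$annotation,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p$drivers <- file.path(dir, "drivers.txt")
  writeLines(cohort$drivers, p$drivers)
  p$planted_umgs <- file.path(dir, "planted_umgs.txt")
  writeLines(cohort$planted_umgs, p$planted_umgs)
  invisible(p)
}
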