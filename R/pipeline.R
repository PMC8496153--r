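#' Run the upward-mobility prioritization pipeline in memory
#'
#' Executes the full analysis on already-loaded objects: network filtering,
#' mutation-matrix construction, per-network propagation, rank-mobility
#' selection, cross-network intersection, optional dependency filtering,
#' ranking validation, impact-score comparison, and positionality
#' categorization against the composite network.
#'
#' @param networks list of `umg_network` objects (one per PPI source).
#' @param variants variant data.frame (see [count_matrix()]).
#' @param gene_lengths named vector or data.frame of gene lengths (bp).
#' @param expression optional FPKM matrix for node filtering.
#' @param dependency optional `dependency_data` for the DM filter and
#'   impact-score comparison.
#' @param drivers optional character vector of known driver genes (used for
#'   ranking validation and positionality).
#' @param cohort cohort label; used to look up `beta` when it is NULL and
#'   to pick cancer-type cell lines in the dependency data.
#' @param beta mobility fraction; defaults from [umg_beta_defaults] via the
#'   cohort label.
#' @param rank_threshold top-rank cutoff T (default 1000).
#' @param depmap_fraction dependency fraction p (default 0.5).
#' @param skip_depmap disable the optional dependency filter.
#' @param alpha,tolerance,max_iterations propagation parameters.
#' @param network_filters optional list (parallel to `networks`) of filter
#'   descriptions: `list(mode = "confidence", threshold =, scale_hint =)`,
#'   `list(mode = "top_fraction", fraction =)`, or `list(mode = "none")`.
#' @param fpkm_threshold,sample_fraction expression-filter parameters.
#' @param keep_classes variant classes retained in the mutation matrix.
#' @param positionality_params list with `score_threshold`,
#'   `degree_threshold`, `zero_floor` for driver stratification.
#' @return Object of class `umg_report`: list with `per_network`, `final`
#'   (intersection with dependency columns), `final_genes` (post-filter),
#'   `criteria`, `enrichment`, `impact_comparison`, `categories`,
#'   `composite`, `provenance`.
#' @export
run_umg_pipeline <- function(networks, variants, gene_lengths,
                             expression = NULL, dependency = NULL,
                             drivers = NULL, cohort = "unknown",
                             beta = NULL, rank_threshold = 1000,
                             depmap_fraction = 0.5, skip_depmap = FALSE,
                             alpha = 0.8, tolerance = 1e-8,
                             max_iterations = 350,
                             network_filters = NULL,
                             fpkm_threshold = 15, sample_fraction = 0.2,
                             keep_classes = c("exonic", "splicing"),
                             positionality_params = list(
                               score_threshold = 0.075,
                               degree_threshold = 150,
                               zero_floor = 0.0015)) {
  stopifnot(is.list(networks), length(networks) >= 1)
  if (is.null(beta)) beta <- default_beta(cohort)
  provenance <- list(cohort = cohort, beta = beta,
                     rank_threshold = rank_threshold,
                     depmap_fraction = depmap_fraction,
                     skip_depmap = skip_depmap, alpha = alpha,
                     tolerance = tolerance,
                     max_iterations = max_iterations, stages = list())

  # stage 1: network filtering
  tags <- make.unique(vapply(networks, `[[`, "", "source_tag"))
  filtered <- vector("list", length(networks))
  for (i in seq_along(networks)) {
    net <- networks[[i]]
    net$source_tag <- tags[i]
    counts <- list(input = c(nodes = network_size(net),
                             edges = igraph::ecount(net$graph)))
    f <- if (!is.null(network_filters)) network_filters[[i]] else
      list(mode = "none")
    net <- switch(f$mode,
      confidence = filter_by_confidence(net, f$threshold,
                                        f$scale_hint %||% 1),
      top_fraction = filter_top_fraction(net, f$fraction),
      none = net,
      stop("unknown filter mode: ", f$mode))
    net <- largest_connected_component(net)
    counts$after_edge_filter_lcc <- c(nodes = network_size(net),
                                      edges = igraph::ecount(net$graph))
    if (!is.null(expression)) {
      net <- filter_by_expression(net, expression, fpkm_threshold,
                                  sample_fraction)
      counts$after_expression_lcc <- c(nodes = network_size(net),
                                       edges = igraph::ecount(net$graph))
    }
    filtered[[i]] <- net
    provenance$stages[[paste0("network_", net$source_tag)]] <- counts
  }

  # stage 2: quantized mutation matrix (cohort-wide, shared by networks)
  mm <- build_mutation_matrix(variants, gene_lengths, keep_classes)
  provenance$stages$mutation_matrix <- list(
    genes = nrow(mm$scores), samples = ncol(mm$scores),
    thresholds = as.list(mm$thresholds))

  # stage 3-4: propagate each network's restriction and select
  per_network <- list()
  for (i in seq_along(filtered)) {
    net <- filtered[[i]]
    prop <- propagate_network(net, mm$scores, alpha, tolerance,
                              max_iterations)
    ranking <- gene_ranking(prop$initial, prop$final)
    umgs <- select_umgs(ranking, beta, rank_threshold)
    enr <- NULL
    if (!is.null(drivers)) {
      rfs <- stats::setNames(ranking$RFS, ranking$gene)
      if (length(intersect(drivers, ranking$gene)) > 0) {
        enr <- rank_enrichment(rfs, drivers)
      }
    }
    per_network[[net$source_tag]] <- list(
      network = net, ranking = ranking, umgs = umgs,
      iterations = prop$iterations, converged = prop$converged,
      dropped_genes = prop$dropped_genes, enrichment = enr)
    provenance$stages[[paste0("propagate_", net$source_tag)]] <- list(
      iterations = prop$iterations, converged = prop$converged,
      n_umgs = nrow(umgs))
  }

  # stage 5: intersection, then the optional dependency filter
  final <- intersect_networks(lapply(per_network, `[[`, "umgs"))
  dm <- NULL
  if (!skip_depmap && !is.null(dependency) && nrow(final) > 0) {
    dm <- depmap_filter(final$gene, dependency, cohort, depmap_fraction)
    final <- merge(final, dm[, c("gene", "DM", "kept", "no_data")],
                   by = "gene", sort = FALSE)
    final <- final[order(final$mean_RFS, final$gene), , drop = FALSE]
    rownames(final) <- NULL
    final_genes <- final$gene[final$kept]
  } else {
    final_genes <- final$gene
  }
  provenance$stages$intersection <- list(
    n_intersect = nrow(final), n_final = length(final_genes))

  # stage 6: impact-score comparison of final genes vs background
  impact_comparison <- NULL
  if (!is.null(dependency) && length(final_genes) >= 2) {
    universe <- Reduce(intersect,
                       lapply(per_network, function(x) x$ranking$gene))
    background <- setdiff(universe, c(final_genes, drivers))
    impact_comparison <- tryCatch(
      compare_groups(final_genes, background, dependency, cohort,
                     assay = names(dependency$assays)[1]),
      error = function(e) NULL)
  }

  # stage 7: positionality on the composite network
  categories <- NULL
  composite <- NULL
  strat <- NULL
  if (length(filtered) >= 2 && !is.null(drivers) &&
      length(final_genes) > 0) {
    composite <- composite_union(filtered)
    is_all <- stats::setNames(rowMeans(mm$scores), rownames(mm$scores))
    strat <- stratify_drivers(
      drivers, is_all, composite,
      score_threshold = positionality_params$score_threshold,
      degree_threshold = positionality_params$degree_threshold,
      zero_floor = positionality_params$zero_floor)
    categories <- categorize_umgs(
      final_genes, strat, is_all, composite,
      zero_floor = positionality_params$zero_floor)
  }

  structure(list(per_network = per_network, final = final,
                 final_genes = final_genes,
                 criteria = list(beta = beta,
                                 rank_threshold = rank_threshold,
                                 depmap_fraction = depmap_fraction),
                 enrichment = lapply(per_network, `[[`, "enrichment"),
                 impact_comparison = impact_comparison,
                 categories = categories, driver_strata = strat,
                 composite = composite, mutation = mm,
                 provenance = provenance),
            class = "umg_report")
}

#' @export
print.umg_report <- function(x, ...) {
  cat(sprintf("umg_report: cohort %s, beta = %g, T = %d\n",
              x$provenance$cohort, x$criteria$beta,
              x$criteria$rank_threshold))
  for (nm in names(x$per_network)) {
    cat(sprintf("  %s: %d genes ranked, %d selected\n", nm,
                nrow(x$per_network[[nm]]$ranking),
                nrow(x$per_network[[nm]]$umgs)))
  }
  cat(sprintf("  final: %d genes after intersection%s\n",
              length(x$final_genes),
              if (!is.null(x$final$kept)) " + dependency filter" else ""))
  invisible(x)
}

#' Run the pipeline from a YAML configuration file
#'
#' Reads every input named in the config, runs [run_umg_pipeline()], and
#' writes the report tables and a provenance JSON to the output directory.
#' Unknown top-level keys are rejected so typos fail before computation.
#'
#' @param config path to a YAML file, or an equivalent named list. Keys:
#'   `cohort`, `beta`, `rank_threshold`, `depmap_fraction`, `skip_depmap`,
#'   `alpha`, `tolerance`, `max_iterations`, `networks` (list of
#'   `path`/`dialect`/`filter`), `variants`, `gene_lengths`, `expression`,
#'   `fpkm_threshold`, `sample_fraction`, `dependency` (named assay CSV
#'   paths plus `annotation`), `drivers`, `positionality`, `out_dir`.
#' @return The `umg_report`, invisibly; artifacts are written to `out_dir`.
#' @export
run_umg_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("cohort", "beta", "rank_threshold", "depmap_fraction",
             "skip_depmap", "alpha", "tolerance", "max_iterations",
             "networks", "variants", "gene_lengths", "expression",
             "fpkm_threshold", "sample_fraction", "keep_classes",
             "dependency", "drivers", "positionality", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in c("networks", "variants", "gene_lengths")) {
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  }
  networks <- lapply(config$networks, function(n) {
    tag <- n$tag %||% sub("\\.[^.]*$", "", basename(n$path))
    read_edge_list(n$path, n$dialect %||% "generic_tsv", source_tag = tag)
  })
  filters <- lapply(config$networks, function(n) {
    n$filter %||% list(mode = "none")
  })
  variants <- read_variants(config$variants)
  gl <- utils::read.delim(config$gene_lengths, stringsAsFactors = FALSE)
  expression <- NULL
  if (!is.null(config$expression)) {
    tab <- utils::read.delim(config$expression, check.names = FALSE,
                             stringsAsFactors = FALSE)
    expression <- as.matrix(tab[, -1, drop = FALSE])
    rownames(expression) <- as.character(tab[[1]])
  }
  dependency <- NULL
  if (!is.null(config$dependency)) {
    dcfg <- config$dependency
    ann <- utils::read.delim(dcfg$annotation, stringsAsFactors = FALSE)
    assays <- lapply(dcfg[setdiff(names(dcfg), "annotation")],
                     read_dependency_matrix)
    names(assays) <- toupper(names(assays))
    dependency <- dependency_data(assays, ann)
  }
  drivers <- if (!is.null(config$drivers)) read_gene_set(config$drivers)
  pos <- config$positionality %||% list()
  report <- run_umg_pipeline(
    networks = networks, variants = variants, gene_lengths = gl,
    expression = expression, dependency = dependency, drivers = drivers,
    cohort = config$cohort %||% "unknown", beta = config$beta,
    rank_threshold = config$rank_threshold %||% 1000,
    depmap_fraction = config$depmap_fraction %||% 0.5,
    skip_depmap = isTRUE(config$skip_depmap),
    alpha = config$alpha %||% 0.8,
    tolerance = config$tolerance %||% 1e-8,
    max_iterations = config$max_iterations %||% 350,
    network_filters = filters,
    fpkm_threshold = config$fpkm_threshold %||% 15,
    sample_fraction = config$sample_fraction %||% 0.2,
    keep_classes = config$keep_classes %||% c("exonic", "splicing"),
    positionality_params = list(
      score_threshold = pos$score_threshold %||% 0.075,
      degree_threshold = pos$degree_threshold %||% 150,
      zero_floor = pos$zero_floor %||% 0.0015))
  if (!is.null(config$out_dir)) write_umg_report(report, config$out_dir)
  invisible(report)
}

#' Write report tables and provenance JSON
#'
#' @param report `umg_report`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_umg_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$per_network)) {
    pn <- report$per_network[[nm]]
    utils::write.table(pn$ranking,
                       file.path(dir, paste0("ranking_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pn$umgs,
                       file.path(dir, paste0("umgs_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$final, file.path(dir, "umgs_final.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$categories)) {
    utils::write.table(report$categories,
                       file.path(dir, "umg_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  prov <- report$provenance
  prov$final_genes <- report$final_genes
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
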