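# Shared fixtures, all built in code. The default synthetic cohort and its
# pipeline report are expensive enough to build once and share across files.

edge_net <- function(from, to, weight, tag = "test") {
  umgnet::umg_network(
    data.frame(from = from, to = to, weight = weight,
               stringsAsFactors = FALSE),
    source_tag = tag)
}

# connected random graph with uniform(0.1, 1] weights; takes the LCC of a
# G(n, p) draw so the result is always connected
random_connected_net <- function(n, p = NULL, tag = "rand") {
  if (is.null(p)) p <- min(1, 2.5 * log(n) / n)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  el <- igraph::as_edgelist(g, names = TRUE)
  net <- edge_net(el[, 1], el[, 2], stats::runif(nrow(el), 0.1, 1), tag)
  umgnet::largest_connected_component(net)
}

random_seed_matrix <- function(net, n_samples = 3, density = 0.3) {
  nodes <- umgnet::network_nodes(net)
  m <- matrix(0, length(nodes), n_samples,
              dimnames = list(nodes, paste0("s", seq_len(n_samples))))
  nz <- stats::runif(length(m)) < density
  m[nz] <- sample(1:4, sum(nz), replace = TRUE)
  m
}

# dependency fixture: one assay, explicit score rows per gene
tiny_dependency <- function(scores, cancer_type = "TT",
                            assay = "CRISPR", annotated = TRUE) {
  stopifnot(is.matrix(scores))
  if (is.null(colnames(scores))) {
    colnames(scores) <- sprintf("L%02d", seq_len(ncol(scores)))
  }
  ann <- data.frame(
    cell_line = colnames(scores),
    cancer_type = if (annotated) cancer_type else "ELSEWHERE",
    stringsAsFactors = FALSE)
  umgnet::dependency_data(stats::setNames(list(scores), assay), ann)
}

# the default cohort and its pipeline report, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- umgnet::generate_cohort(
      umgnet::synthetic_cohort_spec(seed = 42))
  }
  .fixture_cache$cohort
}

default_report <- function() {
  if (is.null(.fixture_cache$report)) {
    co <- default_cohort()
    .fixture_cache$report <- umgnet::run_umg_pipeline(
      networks = co$networks, variants = co$variants,
      gene_lengths = co$gene_lengths, expression = co$expression,
      dependency = co$dependency, drivers = co$drivers,
      cohort = "SYNTH", beta = 0.25)
  }
  .fixture_cache$report
}

# independent brute-force one-sided rank-sum p-value: enumerate every
# assignment of group labels to the pooled values and compare rank sums
brute_force_ranksum_p <- function(ref_values, other_values) {
  pooled <- c(ref_values, other_values)
  k <- length(ref_values)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(k)])
  idx <- utils::combn(length(pooled), k)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  mean(ws <= w_obs + 1e-9)
}

# all permutations of 1..n, one per column
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0
  for (j in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      col <- col + 1
      out[, col] <- append(sub[, j], n, after = pos - 1)
    }
  }
  out
}

# independent brute-force selector: literal restatement of the selection rule
brute_force_select <- function(ranking, beta, T, G_size = nrow(ranking)) {
  out <- character(0)
  for (i in seq_len(nrow(ranking))) {
    if (ranking$RIS[i] - ranking$RFS[i] >= beta * G_size &&
        ranking$RFS[i] <= T) {
      out <- c(out, ranking$gene[i])
    }
  }
  sort(out)
}
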