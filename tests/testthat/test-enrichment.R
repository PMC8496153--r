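test_that("exact enrichment reproduces the 1/20 worked example", {
  ranks <- stats::setNames(1:6, letters[1:6])
  res <- rank_enrichment(ranks, reference = c("a", "b", "c"))
  expect_equal(res$p_value, 0.05)  # 1 / choose(6, 3)
  expect_equal(res$method, "exact")
  expect_equal(res$n_reference, 3)

  # reversed: reference holds the worst ranks -> p well above 0.5
  res <- rank_enrichment(ranks, reference = c("d", "e", "f"))
  expect_gt(res$p_value, 0.5)

  expect_error(rank_enrichment(ranks, "zz"), "no reference")
  expect_error(rank_enrichment(ranks, letters[1:6]), "non-reference")
})

test_that("near-identical rank distributions give p near 0.5", {
  withr::local_seed(31)
  n <- 400
  ranks <- stats::setNames(sample(n), sprintf("g%03d", 1:n))
  # interleaved reference at average positions
  ref <- names(sort(ranks))[seq(1, n, by = 2)]
  res <- rank_enrichment(ranks, ref)
  expect_equal(res$method, "normal_approx")
  expect_gt(res$p_value, 0.3)
  expect_lt(res$p_value, 0.7)
})

test_that("exact mode matches the brute-force permutation oracle with and without ties", {
  cases <- list(
    list(ref = c(1, 2, 3), oth = c(4, 5, 6)),
    list(ref = c(2, 5), oth = c(1, 3, 4, 6)),
    list(ref = c(1, 4, 4), oth = c(2, 4, 6)),       # ties across groups
    list(ref = c(7, 8), oth = c(1, 2, 3)),
    list(ref = c(1.5, 1.5, 3), oth = c(1.5, 4, 5)))
  for (cs in cases) {
    ranks <- stats::setNames(c(cs$ref, cs$oth),
                             sprintf("g%d", seq_along(c(cs$ref, cs$oth))))
    got <- rank_enrichment(ranks, sprintf("g%d", seq_along(cs$ref)))$p_value
    expect_equal(got, brute_force_ranksum_p(cs$ref, cs$oth),
                 tolerance = 1e-12)
  }
})

test_that("exact mode agrees with the stats package on tie-free samples", {
  withr::local_seed(41)
  for (i in 1:10) {
    x <- sample(100, 5)
    y <- sample(setdiff(1:100, x), 6)
    got <- mann_whitney(x, y, alternative = "less")$p_value
    ref <- stats::wilcox.test(x, y, alternative = "less",
                              exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("the impact score reproduces its closed-form examples and stays below 1", {
  all_neg <- matrix(-1, 1, 4, dimnames = list("g", sprintf("L%d", 1:4)))
  dep <- tiny_dependency(all_neg)
  expect_equal(impact_score("g", dep, "TT", "CRISPR")$psi, 5 / 6,
               tolerance = 1e-12)  # 0.8333

  no_neg <- matrix(1, 1, 4, dimnames = list("g", sprintf("L%d", 1:4)))
  expect_equal(impact_score("g", tiny_dependency(no_neg), "TT", "CRISPR")$psi, 0)

  half <- matrix(c(rep(-1, 5), rep(1, 5)), 1, 10,
                 dimnames = list("g", sprintf("L%d", 1:10)))
  expect_equal(impact_score("g", tiny_dependency(half), "TT", "CRISPR")$psi,
               5.5 / 12, tolerance = 1e-12)  # 0.4583

  # psi < 1 strictly and monotone in the number of negative lines
  withr::local_seed(19)
  prev <- -Inf
  for (nneg in 0:12) {
    m <- matrix(c(rep(-0.5, nneg), rep(0.5, 12 - nneg)), 1, 12,
                dimnames = list("g", sprintf("L%02d", 1:12)))
    psi <- impact_score("g", tiny_dependency(m), "TT", "CRISPR")$psi
    expect_lt(psi, 1)
    expect_gt(psi, prev)
    prev <- psi
  }

  # plain-fraction variant equals DM-style proportion
  expect_equal(impact_score("g", tiny_dependency(half), "TT", "CRISPR",
                            variant = "fraction")$psi, 0.5)
  # absent gene is flagged undefined
  expect_true(is.na(impact_score("nope", dep, "TT", "CRISPR")$psi))
})

test_that("group comparison detects a planted viability shift", {
  withr::local_seed(53)
  k <- 12
  genes <- sprintf("g%03d", 1:70)
  umg <- genes[1:35]
  bg <- genes[36:70]
  neg_prob <- ifelse(genes %in% umg, 0.85, 0.3)
  m <- matrix(0.3, 70, k, dimnames = list(genes, sprintf("L%02d", 1:k)))
  neg <- matrix(stats::runif(70 * k) < neg_prob, 70, k)
  m[neg] <- -0.5
  dep <- tiny_dependency(m)
  res <- compare_groups(umg, bg, dep, "TT", "CRISPR")
  expect_lt(res$p_value, 0.05)

  # identical distributions: p near 0.5; reversed shift: p above 0.5
  same <- compare_groups(umg, umg, dep, "TT", "CRISPR")
  expect_gt(same$p_value, 0.4)
  rev <- compare_groups(bg, umg, dep, "TT", "CRISPR")
  expect_gt(rev$p_value, 0.5)
})

test_that("gene set files ignore comments and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# drivers", "TP53", "", "KRAS", "TP53"), path)
  expect_equal(read_gene_set(path), c("TP53", "KRAS"))
})
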