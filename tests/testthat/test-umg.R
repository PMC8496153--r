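test_that("mean scores average across samples", {
  S0 <- matrix(c(2, 0, 0, 0, 0, 0, 0, 0), 2, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  ms <- mean_scores(S0, S0)
  expect_equal(ms$IS, c(0.5, 0))

  Wp <- column_normalize(edge_net("A", "B", 1))
  S0 <- matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "s1"))
  fin <- propagate_closed_form(Wp, S0, alpha = 0.5)
  ms <- mean_scores(S0, fin)
  expect_equal(ms$FS, c(2 / 3, 1 / 3), tolerance = 1e-12)

  expect_error(mean_scores(S0[, 0, drop = FALSE], fin[, 0, drop = FALSE]),
               "zero samples")
})

test_that("ranking is descending with tie-aware average ranks", {
  expect_equal(rank_scores(c(5, 3, 1)), c(1, 2, 3))
  expect_equal(rank_scores(c(5, 5, 1)), c(1.5, 1.5, 3))
  expect_equal(rank_scores(rep(2, 7)), rep(4, 7))  # (|G|+1)/2
  # input-order independence of average ranks
  s <- c(3, 1, 3, 2, 1)
  expect_equal(sort(rank_scores(s)), sort(rank_scores(rev(s))))
  expect_equal(rank_scores(c(1, 2, 3), ties = "first"), c(3, 2, 1))
})

test_that("mobility is the rank difference and sums to zero for permutations", {
  expect_equal(mobility(800, 200), 600)
  expect_equal(mobility(5, 5), 0)
  withr::local_seed(2)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    expect_equal(sum(mobility(sample(n), sample(n))), 0)
  }
})

test_that("selection rule applies beta*|G| jump and top-T boundary inclusively", {
  rk <- data.frame(gene = letters[1:10], IS = 10:1, FS = 0,
                   RIS = 1:10, RFS = c(4:10, 2, 1, 3), stringsAsFactors = FALSE)
  rk$MS <- rk$RIS - rk$RFS
  # gene h: RIS 8, RFS 2 -> MS 6 >= 0.2*10 and RFS <= 3 -> selected
  sel <- select_umgs(rk, beta = 0.2, rank_threshold = 3)
  expect_true("h" %in% sel$gene)
  # the top-initial gene cannot jump upward
  expect_false("a" %in% select_umgs(rk, beta = 0.05, rank_threshold = 10)$gene)

  # boundary: MS exactly beta*|G| is selected; RFS exactly T is selected
  rk2 <- data.frame(gene = c("x", "y"), IS = c(1, 2), FS = c(2, 1),
                    RIS = c(6, 1), RFS = c(4, 6), stringsAsFactors = FALSE)
  rk2$MS <- rk2$RIS - rk2$RFS
  sel <- select_umgs(rk2, beta = 0.2, rank_threshold = 4, G_size = 10)
  expect_equal(sel$gene, "x")  # MS = 2 = 0.2*10, RFS = 4 = T
})

test_that("selection matches a brute-force selector on small universes", {
  withr::local_seed(17)
  for (n in 3:12) {
    for (rep in 1:25) {
      is <- sample(0:4, n, replace = TRUE)
      fs <- stats::runif(n)
      rk <- data.frame(gene = sprintf("g%02d", 1:n), IS = is, FS = fs,
                       RIS = rank_scores(is), RFS = rank_scores(fs),
                       stringsAsFactors = FALSE)
      rk$MS <- rk$RIS - rk$RFS
      for (beta in c(0.1, 0.25, 0.5)) {
        for (T in c(1, ceiling(n / 2), n)) {
          expect_equal(sort(select_umgs(rk, beta, T)$gene),
                       brute_force_select(rk, beta, T))
        }
      }
    }
  }
})

test_that("raising beta or lowering T never adds genes", {
  withr::local_seed(23)
  n <- 50
  is <- sample(0:4, n, replace = TRUE)
  fs <- stats::runif(n)
  rk <- data.frame(gene = sprintf("g%02d", 1:n), IS = is, FS = fs,
                   RIS = rank_scores(is), RFS = rank_scores(fs),
                   stringsAsFactors = FALSE)
  rk$MS <- rk$RIS - rk$RFS
  betas <- c(0.05, 0.1, 0.2, 0.4)
  Ts <- c(50, 25, 10, 5)
  for (i in seq_along(betas)[-1]) {
    expect_true(all(select_umgs(rk, betas[i], 25)$gene %in%
                      select_umgs(rk, betas[i - 1], 25)$gene))
    expect_true(all(select_umgs(rk, 0.1, Ts[i])$gene %in%
                      select_umgs(rk, 0.1, Ts[i - 1])$gene))
  }
})

test_that("cohort beta defaults follow the published assignment", {
  expect_equal(default_beta("BRCA"), 0.25)
  expect_equal(default_beta("KIRC"), 0.20)
  expect_equal(default_beta("READ"), 0.15)
  expect_equal(default_beta("THCA"), 0.05)
  expect_error(default_beta("NOPE"), "supply beta")
})

test_that("dependency filter takes the max negative fraction across assays", {
  crispr <- matrix(c(-1, -1, -1, 1, 1), 1, 5,
                   dimnames = list("g", sprintf("C%d", 1:5)))
  rnai <- matrix(c(-1, -1, 1, 1, 1), 1, 5,
                 dimnames = list("g", sprintf("R%d", 1:5)))
  ann <- data.frame(cell_line = c(colnames(crispr), colnames(rnai)),
                    cancer_type = "TT", stringsAsFactors = FALSE)
  dep <- dependency_data(list(CRISPR = crispr, RNAi = rnai), ann)
  out <- depmap_filter("g", dep, "TT", p = 0.5)
  expect_equal(out$DM, 0.6)   # max(3/5, 2/5)
  expect_true(out$kept)

  none <- dependency_data(list(CRISPR = abs(crispr), RNAi = abs(rnai)), ann)
  out <- depmap_filter("g", none, "TT", p = 0.5)
  expect_equal(out$DM, 0)
  expect_false(out$kept)

  # unannotated cancer type falls back to all cell lines
  out_fb <- depmap_filter("g", dep, "UNREPRESENTED", p = 0.5)
  expect_equal(out_fb$DM, 0.6)

  # gene with no dependency data passes with a flag
  out <- depmap_filter(c("g", "missing"), dep, "TT", p = 0.5)
  expect_true(out$kept[out$gene == "missing"])
  expect_true(out$no_data[out$gene == "missing"])
  expect_false(out$no_data[out$gene == "g"])
})

test_that("network intersection keeps shared genes ordered by mean RFS", {
  l1 <- data.frame(gene = c("A", "B", "C"), RFS = c(1, 2, 3))
  l2 <- data.frame(gene = c("B", "C", "D"), RFS = c(9, 1, 2))
  out <- intersect_networks(list(l1, l2))
  expect_equal(out$gene, c("C", "B"))  # mean RFS 2 vs 5.5
  expect_equal(out$mean_RFS, c(2, 5.5))

  single <- intersect_networks(list(l1))
  expect_equal(single$gene, c("A", "B", "C"))

  expect_warning(out <- intersect_networks(list(
    data.frame(gene = "A", RFS = 1), data.frame(gene = "B", RFS = 1))),
    "empty")
  expect_equal(nrow(out), 0)
})
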