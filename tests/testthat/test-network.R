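test_that("edge lists deduplicate undirected edges, drop self-loops, keep max weight", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "B\tA\t0.9"), path)
  net <- read_edge_list(path)
  expect_equal(nrow(network_edges(net)), 1)
  expect_equal(network_edges(net)$weight, 0.9)

  writeLines(c("A\tA\t0.8", "A\tB\t0.7"), path)
  net <- read_edge_list(path)
  e <- network_edges(net)
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$from, e$to), c("A", "B"))

  # exhaustive check on all 2-row files over {A,B} with weights {0.5, 0.6}:
  # whatever the orientation/order, a duplicated A-B edge keeps the max
  for (o1 in list(c("A", "B"), c("B", "A"))) {
    for (o2 in list(c("A", "B"), c("B", "A"))) {
      for (w in list(c(0.5, 0.6), c(0.6, 0.5))) {
        writeLines(c(paste(o1[1], o1[2], w[1], sep = "\t"),
                     paste(o2[1], o2[2], w[2], sep = "\t")), path)
        net <- read_edge_list(path)
        expect_equal(network_edges(net)$weight, 0.6)
      }
    }
  }
})

test_that("edge list reader detects headers and reports malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", "A\tB\t700"), path)
  net <- read_edge_list(path, dialect = "string_style")
  expect_equal(network_edges(net)$weight, 700)

  writeLines(c("A\tB\t0.9", "brokenrow"), path)
  expect_error(read_edge_list(path), "line 2")

  writeLines(character(0), path)
  expect_error(read_edge_list(path), "empty")
})

test_that("confidence filter keeps the inclusive boundary and rescales 1000-scale scores", {
  net <- edge_net(c("A", "B", "C"), c("B", "C", "D"), c(0.95, 0.70, 0.69))
  kept <- filter_by_confidence(net, 0.7)
  expect_equal(nrow(network_edges(kept)), 2)
  expect_true(all(network_edges(kept)$weight >= 0.7))

  expect_warning(id <- filter_by_confidence(net, 0), "outside")
  expect_equal(network_edges(id), network_edges(net))

  scaled <- edge_net(c("A", "B", "C"), c("B", "C", "D"), c(950, 700, 699))
  kept <- filter_by_confidence(scaled, 0.7, scale_hint = 1000)
  expect_equal(network_edges(kept)$weight,
               network_edges(filter_by_confidence(scaled, 700))$weight)
  expect_equal(nrow(network_edges(kept)), 2)
})

test_that("top-fraction filter keeps ceil(f|E|) edges and expands ties at the cutoff", {
  nodes <- sprintf("N%02d", 1:40)
  net <- edge_net(nodes[1:20], nodes[21:40], seq(0.05, 1, length.out = 20))
  kept <- filter_top_fraction(net, 0.10)
  expect_equal(nrow(network_edges(kept)), 2)
  expect_equal(sort(network_edges(kept)$weight), sort(seq(0.05, 1, length.out = 20))[19:20])

  expect_equal(network_edges(filter_top_fraction(net, 1)), network_edges(net))

  tied <- edge_net(sprintf("A%d", 1:10), sprintf("B%d", 1:10),
                   c(5, 5, 5, 4, 3, 2, 1, 0.5, 0.4, 0.3))
  kept <- filter_top_fraction(tied, 0.10)
  expect_equal(nrow(network_edges(kept)), 3)  # nominal 1, ties expand to 3
  # brute-force: sort weights, find cutoff, count >= cutoff
  w <- c(5, 5, 5, 4, 3, 2, 1, 0.5, 0.4, 0.3)
  expect_equal(nrow(network_edges(kept)),
               sum(w >= sort(w, decreasing = TRUE)[ceiling(0.1 * 10)]))
})

test_that("top-fraction filtering nests monotonically and is idempotent", {
  withr::local_seed(7)
  net <- random_connected_net(60)
  fracs <- c(0.1, 0.3, 0.5, 0.8, 1)
  edge_key <- function(n) with(network_edges(n), paste(from, to))
  for (i in seq_along(fracs)[-1]) {
    small <- filter_top_fraction(net, fracs[i - 1])
    big <- filter_top_fraction(net, fracs[i])
    expect_true(all(edge_key(small) %in% edge_key(big)))
  }
  once <- filter_top_fraction(net, 0.3)
  expect_equal(network_edges(filter_top_fraction(once, 1)),
               network_edges(once))
  conf_once <- filter_by_confidence(net, 0.5)
  expect_equal(network_edges(suppressWarnings(
    filter_by_confidence(conf_once, 0.5))), network_edges(conf_once))
})

test_that("largest connected component picks the biggest component, deterministic ties", {
  net <- edge_net(c("A", "B", "C", "D", "X", "Y"),
                  c("B", "C", "D", "E", "Y", "Z"),
                  rep(1, 6))  # components {A..E} (5) and {X,Y,Z} (3)
  lcc <- largest_connected_component(net)
  expect_setequal(network_nodes(lcc), c("A", "B", "C", "D", "E"))
  expect_true(igraph::is_connected(lcc$graph))

  expect_equal(network_edges(largest_connected_component(lcc)),
               network_edges(lcc))

  tie <- edge_net(c("AAA", "M1", "B1", "B2"), c("M1", "M2", "B2", "B3"),
                  rep(1, 4))  # two components of size 3
  expect_true("AAA" %in% network_nodes(largest_connected_component(tie)))
})

test_that("expression filter applies FPKM > t in > fraction of samples, strictly", {
  net <- edge_net(c("A", "B"), c("B", "C"), c(1, 1))
  expr <- matrix(0, 3, 10, dimnames = list(c("A", "B", "C"), NULL))
  expr["A", 1:3] <- 20   # 0.3 > 0.2 -> retained
  expr["B", ] <- 50
  expr["C", 1:2] <- 20   # 0.2 is not > 0.2 -> removed
  out <- filter_by_expression(net, expr, 15, 0.2)
  expect_setequal(network_nodes(out), c("A", "B"))

  # 4-node star whose hub is unexpressed: leaves survive the expression rule
  # but are left isolated, so the filter chain surfaces an error
  star <- edge_net(rep("H", 3), c("A", "B", "C"), rep(1, 3))
  sexpr <- matrix(50, 4, 10, dimnames = list(c("H", "A", "B", "C"), NULL))
  sexpr["H", ] <- 1
  expect_error(filter_by_expression(star, sexpr, 15, 0.2))

  # genes absent from the expression matrix are removed
  part <- matrix(50, 2, 10, dimnames = list(c("A", "B"), NULL))
  out <- filter_by_expression(net, part, 15, 0.2)
  expect_setequal(network_nodes(out), c("A", "B"))

  expect_error(filter_by_expression(net, expr[, 0, drop = FALSE]), "zero samples")
})

test_that("composite union takes node/edge union with max rescaled weight", {
  n1 <- edge_net(c("A"), c("B"), 1)
  n2 <- edge_net(c("B"), c("C"), 1)
  u <- composite_union(list(n1, n2))
  expect_setequal(network_nodes(u), c("A", "B", "C"))
  expect_equal(nrow(network_edges(u)), 2)

  same <- edge_net(c("A", "B"), c("B", "C"), c(0.5, 0.9))
  u <- composite_union(list(same, same))
  expect_equal(network_edges(u)[, c("from", "to")],
               network_edges(same)[, c("from", "to")])

  # shared edge X-Y rescales to 0.4 in net1 and 0.9 in net2 -> keeps 0.9
  net1 <- edge_net(c("A", "X", "C"), c("B", "Y", "D"), c(1, 3, 6))
  net2 <- edge_net(c("E", "X", "G"), c("F", "Y", "H"), c(1, 10, 11))
  u <- composite_union(list(net1, net2))
  e <- network_edges(u)
  expect_equal(e$weight[e$from == "X" & e$to == "Y"], 0.9)
  # node set is the union of the inputs
  expect_setequal(network_nodes(u),
                  union(network_nodes(net1), network_nodes(net2)))
})
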