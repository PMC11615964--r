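test_that("WS generator matches the lattice and density contracts", {
  set.seed(1)
  g <- make_ws(100, 10, 0.1)
  expect_equal(igraph::ecount(g$graph), 500)
  expect_equal(igraph::edge_density(g$graph), 500 / choose(100, 2))

  lattice <- make_ws(100, 10, 0)
  expect_true(all(igraph::degree(lattice$graph) == 10))

  cl_lattice <- igraph::transitivity(lattice$graph, type = "global")
  cl_random <- mean(replicate(10, {
    igraph::transitivity(make_ws(100, 10, 1)$graph, type = "global")
  }))
  expect_lt(cl_random, cl_lattice / 2)

  expect_error(make_ws(100, 9, 0.1), "even")
  expect_error(make_ws(10, 10, 0.1), "even|n")
})

test_that("ER generator honours the edge probability", {
  set.seed(2)
  mean_deg <- mean(replicate(20, mean(igraph::degree(make_er(100, 0.1)$graph))))
  expect_equal(mean_deg, 99 * 0.1, tolerance = 0.05)
  expect_error(make_er(100, 0), "p_edge")
  full <- make_er(20, 1)
  expect_equal(igraph::ecount(full$graph), choose(20, 2))
})

test_that("BA generator has the documented edge count and heavy tail", {
  set.seed(3)
  g <- make_ba(100, 5)
  # vertices 2..6 attach 1..4 edges, the remaining 94 attach 5 each
  expect_equal(igraph::ecount(g$graph), 1 + 2 + 3 + 4 + 95 * 5)
  expect_equal(igraph::edge_density(g$graph), 485 / choose(100, 2),
               tolerance = 1e-12)

  tree <- make_ba(50, 1)
  expect_equal(igraph::ecount(tree$graph), 49)

  v_ba <- mean(replicate(10, var(igraph::degree(make_ba(100, 5)$graph))))
  v_er <- mean(replicate(10, var(igraph::degree(make_er(100, 0.1)$graph))))
  expect_gt(v_ba, 2 * v_er)
})

test_that("GM family keeps size fixed and interpolates heterogeneity", {
  set.seed(4)
  counts <- vapply(c(0, 0.5, 1), function(k) {
    igraph::ecount(make_gm(100, 10, k)$graph)
  }, numeric(1))
  expect_true(length(unique(counts)) == 1)

  v0 <- mean(replicate(10, var(igraph::degree(make_gm(100, 10, 0)$graph))))
  v1 <- mean(replicate(10, var(igraph::degree(make_gm(100, 10, 1)$graph))))
  expect_gt(v0, 2 * v1)  # heterogeneity escalates as kappa decreases

  v_ba <- mean(replicate(10, var(igraph::degree(make_ba(100, 5)$graph))))
  expect_gt(v0, v_ba / 3)  # kappa = 0 is in the scale-free regime

  expect_error(make_gm(100, 10, 1.5), "kappa")
})

test_that("LFR-style benchmark meets the community and mixing contracts", {
  set.seed(5)
  g <- make_lfr()
  expect_equal(length(unique(g$communities)), 3)
  sizes <- table(g$communities)
  expect_true(all(sizes >= 30 & sizes <= 50))
  expect_equal(sum(sizes), 100)
  expect_true(igraph::is_connected(g$graph))

  el <- igraph::as_edgelist(g$graph, names = FALSE)
  mu_hat <- mean(g$communities[el[, 1]] != g$communities[el[, 2]])
  expect_equal(mu_hat, 0.1, tolerance = 0.07)
  expect_equal(mean(igraph::degree(g$graph)), 10, tolerance = 0.2)

  g0 <- make_lfr(mu = 0)
  el0 <- igraph::as_edgelist(g0$graph, names = FALSE)
  expect_true(all(g0$communities[el0[, 1]] == g0$communities[el0[, 2]]))
})

test_that("the karate fixture carries the two factions", {
  k <- load_fixture("karate")
  expect_equal(igraph::vcount(k$graph), 34)
  expect_equal(igraph::ecount(k$graph), 78)
  expect_equal(sort(unique(k$communities)), c(1L, 2L))
  expect_equal(unname(table(k$communities)), c(17L, 17L), ignore_attr = TRUE)

  expect_error(load_fixture("football"), "not bundled")
  expect_error(load_fixture("petersen"), "arg")
})

test_that("graph files round-trip through edge list and GML", {
  el_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 2", "2 0"), el_path)
  tri <- read_graph_file(el_path, "edgelist")
  expect_equal(igraph::vcount(tri$graph), 3)
  expect_equal(igraph::ecount(tri$graph), 3)

  set.seed(6)
  g <- make_ws(30, 4, 0.2)
  gml <- withr::local_tempfile(fileext = ".gml")
  write_graph_file(g, gml, "gml")
  back <- read_graph_file(gml, "gml")
  expect_true(igraph::isomorphic(g$graph, back$graph))

  out_el <- withr::local_tempfile(fileext = ".txt")
  write_graph_file(g, out_el, "edgelist")
  back2 <- read_graph_file(out_el, "edgelist")
  expect_true(igraph::isomorphic(g$graph, back2$graph))
})

test_that("community files are validated against the graph", {
  el_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 2", "2 0"), el_path)
  comm_ok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1", "1\t1", "2\t2"), comm_ok)
  g <- read_graph_file(el_path, "edgelist", communities_path = comm_ok)
  expect_equal(g$communities, c(1L, 1L, 2L))

  comm_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1", "1\t1", "7\t2"), comm_bad)
  expect_error(read_graph_file(el_path, "edgelist", communities_path = comm_bad),
               "node id not present")
})

test_that("generators are deterministic under a fixed seed", {
  for (gen in list(function() make_ws(60, 6, 0.3), function() make_er(60, 0.1),
                   function() make_ba(60, 3), function() make_gm(60, 6, 0.5),
                   function() make_lfr())) {
    set.seed(99); a <- gen()
    set.seed(99); b <- gen()
    expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  }
})
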