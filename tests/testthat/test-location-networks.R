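test_that("edge lists parse, collapse duplicates, and reject self-loops", {
  path <- withr::local_tempfile(fileext = ".edges")

  writeLines(c("0 1", "1 2"), path)
  g <- read_edge_list(path)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  writeLines(c("0 1", "1 0"), path)
  expect_equal(igraph::ecount(read_edge_list(path)), 1)

  writeLines(c("# a comment", "", "0 1", "0 1"), path)
  expect_equal(igraph::ecount(read_edge_list(path)), 1)

  writeLines("0 0", path)
  expect_error(read_edge_list(path), "self-loop")

  writeLines("0 5", path)
  expect_error(read_edge_list(path, n_nodes = 3), "out of range")

  writeLines("0 x", path)
  expect_error(read_edge_list(path), "parse")
})

test_that("write/read round-trips arbitrary graphs including isolated nodes", {
  path <- withr::local_tempfile(fileext = ".edges")

  p2 <- generate_path(3)
  write_edge_list(p2, path)
  expect_equal(length(grep("^[0-9]", readLines(path))), 2)

  empty <- igraph::make_empty_graph(4, directed = FALSE)
  write_edge_list(empty, path)
  expect_true(all(grepl("^#", readLines(path)))) # header comments only
  back <- read_edge_list(path)
  expect_equal(igraph::vcount(back), 4)
  expect_equal(igraph::ecount(back), 0)

  g <- generate_er(100, 0.05, seed = 71)
  write_edge_list(g, path)
  h <- read_edge_list(path)
  expect_equal(igraph::vcount(h), igraph::vcount(g))
  canon <- function(x) {
    el <- igraph::as_edgelist(x, names = FALSE)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el[order(el[, 1], el[, 2]), ]
  }
  expect_equal(canon(h), canon(g))
})

test_that("node attribute tables round-trip with positions", {
  path <- withr::local_tempfile(fileext = ".csv")
  f <- sample_attractiveness(6, seed = 2)
  pos <- cbind(runif(6), runif(6))
  write_node_attributes(f, path, positions = pos)
  tbl <- read_node_attributes(path)
  expect_named(tbl, c("node", "f", "x", "y"))
  expect_equal(tbl$f, as.numeric(f), tolerance = 1e-12)
  expect_equal(tbl$node, 1:6)
})

test_that("Erdos-Renyi generator hits exact edge counts at the extremes and binomial means", {
  expect_equal(igraph::ecount(generate_er(5, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(generate_er(5, 1, seed = 1)), 10)
  expect_error(generate_er(0, 0.5), "positive")
  expect_error(generate_er(5, 1.5), "0, 1")

  # mean edge count over seeds vs Binomial(n(n-1)/2, p)
  counts <- vapply(1:200, function(s) igraph::ecount(generate_er(1000, 0.01, seed = s)), 0)
  expected <- 499500 * 0.01
  se <- sqrt(499500 * 0.01 * 0.99) / sqrt(200)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # determinism under a fixed seed, and no RNG-state side effects
  g1 <- generate_er(50, 0.1, seed = 9)
  state <- .Random.seed
  g2 <- generate_er(50, 0.1, seed = 9)
  expect_identical(state, .Random.seed)
  expect_equal(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("Barabasi-Albert generator grows trees at m = 1 with a power-law tail", {
  expect_equal(igraph::ecount(generate_ba(100, 1, seed = 4)), 99)
  expect_equal(igraph::ecount(generate_ba(2, 1, seed = 4)), 1)
  expect_error(generate_ba(5, 5), "m < n")

  g <- generate_ba(1e4, 1, seed = 8)
  tab <- table(igraph::degree(g))
  k <- as.integer(names(tab))
  pk <- as.numeric(tab) / 1e4
  sel <- k >= 2 & k <= 50
  slope <- unname(coef(lm(log(pk[sel]) ~ log(k[sel])))[2])
  # log-log regression on the raw pmf flattens the true -3 exponent a bit
  expect_lt(abs(slope + 3), 0.5)
})

test_that("Voronoi adjacency gives the Delaunay triangle at n = 3 and is connected and planar", {
  tri <- generate_voronoi(3, seed = 21)
  expect_equal(igraph::ecount(tri), 3)

  for (s in 1:5) {
    n <- c(5, 10, 25, 50, 40)[s]
    g <- generate_voronoi(n, seed = 100 + s)
    expect_true(igraph::is_connected(g))
    expect_lte(igraph::ecount(g), 3 * n - 6)
    expect_equal(length(igraph::V(g)$x), n)
  }

  g1 <- generate_voronoi(12, seed = 5)
  g2 <- generate_voronoi(12, seed = 5)
  expect_equal(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("attractiveness construction validates, normalizes, and is deterministic", {
  expect_error(as_attractiveness(c(0.5, 0)), "positive")
  expect_error(as_attractiveness(numeric(0)), "at least one")
  expect_equal(sum(as_attractiveness(runif(20, 1, 5))), 1, tolerance = 1e-12)

  expect_equal(as.numeric(sample_attractiveness(1, seed = 3)), 1)
  f <- sample_attractiveness(50, low = 1, high = 100, seed = 6)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # bounds implied by rescaling the extreme draws
  expect_true(all(f > 1 / (1 + 49 * 100)))
  expect_true(all(f < 100 / (100 + 49 * 1)))
  expect_equal(
    as.numeric(sample_attractiveness(50, seed = 6)),
    as.numeric(f)
  )
})

test_that("degree moments are exact and satisfy Jensen", {
  p3 <- generate_path(3) # degrees 1, 2, 1
  m <- degree_moments(p3)
  expect_equal(m$mean_k, 4 / 3)
  expect_equal(m$mean_k2, 2)

  ring <- igraph::make_ring(10) # 2-regular
  mr <- degree_moments(ring)
  expect_equal(mr$mean_k2, mr$mean_k^2)

  g <- generate_er(1000, 0.01, seed = 31)
  mg <- degree_moments(g)
  se <- sqrt(999 * 0.01 * 0.99 / 1000)
  expect_lt(abs(mg$mean_k - 9.99), 3 * se)
  expect_gte(mg$mean_k2, mg$mean_k^2)

  expect_error(as_degree_moments(10, 3, 8), "valid pair")
})
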