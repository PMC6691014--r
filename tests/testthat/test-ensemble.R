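test_that("ensembles are deterministic under a base seed and average correctly", {
  a <- generate_er(80, 0.05, seed = 201)
  b <- fixture_b()
  f <- fixture_f()
  e1 <- run_ensemble(a, b, f, 0.5, n_realizations = 5, seed = 202)
  e2 <- run_ensemble(a, b, f, 0.5, n_realizations = 5, seed = 202)
  expect_identical(e1$phi_mean, e2$phi_mean)
  expect_identical(e1$gamma_mean, e2$gamma_mean)
  expect_equal(sum(e1$phi_mean), 80)
  expect_equal(gamma_total(e1$gamma_mean), igraph::ecount(a))
  expect_true(all(e1$phi_se >= 0, na.rm = TRUE))

  # a fresh network A per realization: averaged moments, labeled regime
  gen <- function(seed) generate_er(80, 0.05, seed = seed)
  e3 <- run_ensemble(NULL, b, f, 0.5, n_realizations = 4, seed = 203, a_generator = gen)
  expect_true(e3$regenerated_a)
  expect_false(e1$regenerated_a)
  expect_equal(e3$moments$n_nodes, 80)
})

test_that("comparison tables produce exact z-scores and self-consistent fractions", {
  a <- generate_er(100, 0.04, seed = 211)
  b <- fixture_b()
  f <- fixture_f()
  ens <- run_ensemble(a, b, f, 1, n_realizations = 30, seed = 212)
  pred <- embedding_prediction(a, b, f, 1)
  cmp <- compare_tables(ens, pred)

  # z is (mean - predicted) / SE entrywise wherever defined
  ok <- is.na(cmp$phi$excluded)
  expect_equal(
    cmp$phi$z[ok],
    (cmp$phi$sim_mean[ok] - cmp$phi$predicted[ok]) / cmp$phi$sim_se[ok]
  )
  # recompute the summary fractions independently from the emitted table
  g <- glance(cmp)
  expect_equal(g$frac_phi_z_lt3, mean(abs(cmp$phi$z[ok]) < 3))
  okg <- is.na(cmp$gamma$excluded)
  expect_equal(g$frac_gamma_z_lt3, mean(abs(cmp$gamma$z[okg]) < 3))
  expect_equal(nrow(cmp$gamma), 10 * 11 / 2)
  expect_true(any(cmp$gamma$self_loop))

  # a prediction equal to the simulated mean gives z = 0
  pred0 <- pred
  pred0$phi_mean <- ens$phi_mean
  pred0$gamma_mean <- ens$gamma_mean
  cmp0 <- compare_tables(ens, pred0)
  expect_true(all(abs(cmp0$phi$z[is.na(cmp0$phi$excluded)]) < 1e-12))

  # mismatched q is refused
  pred_wrong <- embedding_prediction(a, b, f, 0.5)
  expect_error(compare_tables(ens, pred_wrong), "different q")
})

test_that("trace summaries aggregate only runs still active at each checkpoint", {
  a <- generate_er(60, 0.05, seed = 221)
  b <- fixture_b()
  f <- fixture_f()
  ens <- run_ensemble(a, b, f, 1, n_realizations = 8, seed = 222, trace = TRUE)
  st <- summarize_traces(ens$traces, at = c(0, 2, 5))
  expect_equal(st$n_runs[1], 8)
  expect_equal(st$k1_mean[1], degree_moments(a)$mean_k)
  expect_equal(st$k1_se[1], 0)
  expect_true(all(st$eta_mean <= 60))
})

test_that("the pipeline runs end to end, deterministically, and writes artifacts", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(
    network_a = list(generator = "er", n = 60, p = 0.05),
    network_b = list(generator = "voronoi", n = 8),
    attractiveness = list(low = 1, high = 10),
    q = c(0, 1),
    n_realizations = 4,
    seed = 77,
    ode_step = 0.2
  )
  res1 <- run_pipeline(config, out_dir = out1)
  res2 <- run_pipeline(config, out_dir = out2)
  expect_named(res1$comparisons, c("0", "1"))
  expect_equal(res1$report$frac_phi_z_lt3, res2$report$frac_phi_z_lt3)
  expect_identical(
    res1$ensembles[["1"]]$phi_mean,
    res2$ensembles[["1"]]$phi_mean
  )
  for (fn in c(
    "config.yaml", "network_b.edges", "attractiveness.csv",
    "compare_phi_q0.csv", "compare_gamma_q1.csv",
    "predicted_phi_q1.csv", "predicted_gamma_q0.csv", "report.json"
  )) {
    expect_true(file.exists(file.path(out1, fn)), label = fn)
  }
  # the B artifacts round-trip
  b_back <- read_edge_list(file.path(out1, "network_b.edges"))
  expect_equal(igraph::vcount(b_back), 8)
})

test_that("pipeline configs validate and read from YAML with overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    network_a = list(generator = "er", n = 50, p = 0.1),
    q = list(0.5), n_realizations = 2, seed = 3
  ), path)
  cfg <- read_run_config(path, overrides = list(n_realizations = 5))
  expect_equal(cfg$n_realizations, 5)
  expect_equal(cfg$q, 0.5)
  expect_equal(cfg$network_b$n, 50L) # default filled in

  # unquoted `n:` keys survive YAML 1.1 boolean coercion
  writeLines(c(
    "network_a: {generator: er, n: 40, p: 0.1}",
    "network_b: {generator: voronoi, n: 9}",
    "q: [1]"
  ), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$network_a$n, 40L)
  expect_equal(cfg2$network_b$n, 9L)

  ref <- system.file("extdata/reference_experiment.yaml", package = "flexembed")
  cfg3 <- read_run_config(ref)
  expect_equal(cfg3$network_a$n, 1000L)
  expect_equal(cfg3$network_b$n, 50L)
  expect_equal(cfg3$q, c(0, 0.5, 1))

  expect_error(validate_run_config(list(q = c(-0.1))), "\\[0, 1\\]")
  expect_error(
    validate_run_config(list(network_a = list(path = "/no/such/file"))),
    "does not exist"
  )
})

test_that("realization artifacts are written in diffable form", {
  a <- generate_er(40, 0.08, seed = 231)
  b <- fixture_b()
  f <- fixture_f()
  r <- run_embedding(a, b, f, 0.5, seed = 232)
  dir <- withr::local_tempdir()
  write_realization(r, dir, prefix = "demo")
  phi <- read.csv(file.path(dir, "demo_phi.csv"))
  expect_equal(phi$phi, r$phi)
  gam <- read.csv(file.path(dir, "demo_gamma.csv"))
  expect_equal(sum(gam$weight), igraph::ecount(a))
  meta <- jsonlite::read_json(file.path(dir, "demo_meta.json"))
  expect_equal(meta$n_steps, r$n_steps)
})

test_that("tidiers and autoplots return well-formed objects", {
  a <- generate_er(60, 0.05, seed = 241)
  b <- fixture_b()
  f <- fixture_f()
  r <- run_embedding(a, b, f, 1, seed = 242)
  expect_named(
    tidy(r),
    c("node", "phi", "self_loop_weight", "strength")
  )
  expect_equal(glance(r)$n_steps, r$n_steps)

  traj <- integrate_moments(degree_moments(a))
  expect_true(all(c("t", "moment", "value") %in% names(tidy(traj))))
  expect_s3_class(autoplot(traj), "ggplot")

  ens <- run_ensemble(a, b, f, 1, n_realizations = 4, seed = 243)
  cmp <- compare_tables(ens, embedding_prediction(a, b, f, 1))
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(autoplot(r, f), "ggplot")
  long <- tidy(cmp)
  expect_true(all(c("component", "entry", "z") %in% names(long)))
})
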