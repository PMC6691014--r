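make_pred_inputs <- function(n_a = 300, p = 0.02, n_b = 10) {
  a <- generate_er(n_a, p, seed = 101)
  b <- generate_voronoi(n_b, seed = 102)
  f <- sample_attractiveness(n_b, seed = 103)
  s <- moment_summaries(integrate_moments(degree_moments(a)))
  C <- transition_matrix(b, f)
  list(
    a = a, b = b, f = f, s = s, C = C,
    v0 = stationary_distribution(C),
    omega = function(q) walk_propagator(C, q)
  )
}

test_that("population predictions hit the closed forms and conserve N_A", {
  x <- make_pred_inputs()
  n_a <- x$s$n_nodes

  expect_equal(predict_populations(x$s, x$f, 1), n_a * as.numeric(x$f))

  # edgeless A: no walks happen at any q
  s0 <- moment_summaries(integrate_moments(as_degree_moments(100, 0, 0)))
  for (q in c(0, 0.5, 1)) {
    phi <- predict_populations(s0, x$f, q,
      omega = x$omega(max(q, 0.5)), v0 = x$v0
    )
    expect_equal(phi, 100 * as.numeric(x$f), tolerance = 1e-9)
  }

  for (q in c(0, 0.25, 0.5, 0.75, 1)) {
    phi <- predict_populations(x$s, x$f, q,
      omega = if (q > 0 && q < 1) x$omega(q) else NULL,
      v0 = if (q == 0) x$v0 else NULL
    )
    expect_equal(sum(phi), n_a, tolerance = 1e-8 * n_a)
    expect_true(all(phi >= 0))
  }

  expect_error(predict_populations(x$s, x$f, 0.5), "omega")
  expect_error(predict_populations(x$s, x$f, 0), "v0")
})

test_that("synchronous matrix is symmetric with total mass alpha at every q", {
  x <- make_pred_inputs()
  alpha <- x$s$alpha

  psi1 <- synchronous_matrix(x$s, x$f, 1)
  expect_equal(psi1, diag(alpha * as.numeric(x$f)), tolerance = 1e-12)

  for (q in c(0, 0.3, 0.8, 1)) {
    psi <- synchronous_matrix(x$s, x$f, q,
      omega = if (q > 0 && q < 1) x$omega(q) else NULL,
      v0 = if (q == 0) x$v0 else NULL
    )
    expect_true(isSymmetric(psi))
    expect_true(all(psi >= 0))
    expect_equal(gamma_total(psi), alpha, tolerance = 1e-8 * alpha)
  }

  s0 <- moment_summaries(integrate_moments(as_degree_moments(100, 0, 0)))
  expect_equal(synchronous_matrix(s0, x$f, 1), matrix(0, 10, 10), ignore_attr = TRUE)
})

test_that("stub vectors are nonnegative with total beta + gamma at every q", {
  x <- make_pred_inputs()
  total <- x$s$beta + x$s$gamma

  expect_equal(
    stub_vector(x$s, x$f, 1),
    total * as.numeric(x$f)
  )

  for (q in c(0, 0.3, 0.8, 1)) {
    st <- stub_vector(x$s, x$f, q,
      omega = if (q > 0 && q < 1) x$omega(q) else NULL,
      v0 = if (q == 0) x$v0 else NULL
    )
    expect_true(all(st >= 0))
    expect_equal(sum(st), total, tolerance = 1e-8 * total)
  }

  s0 <- moment_summaries(integrate_moments(as_degree_moments(100, 0, 0)))
  expect_equal(stub_vector(s0, x$f, 0.5, omega = x$omega(0.5)), rep(0, 10))
})

test_that("embedded-adjacency predictions conserve edge mass and match the q = 1 shortcut", {
  x <- make_pred_inputs()
  e_mass <- x$s$n_nodes * x$s$mean_k / 2

  for (q in c(0, 0.25, 0.5, 0.75, 1)) {
    gm <- predict_embedded(x$s, x$f, q,
      omega = if (q > 0 && q < 1) x$omega(q) else NULL,
      v0 = if (q == 0) x$v0 else NULL
    )
    expect_true(isSymmetric(gm))
    expect_true(all(gm >= 0))
    expect_equal(gamma_total(gm), e_mass, tolerance = 1e-8)
  }

  # the q = 1 closed form must equal the general assembly with a vanishing
  # propagator: off-diagonal weight depends only on f and A's mean degree
  fn <- as.numeric(x$f)
  alpha <- x$s$alpha
  g1 <- predict_embedded(x$s, x$f, 1)
  general <- synchronous_matrix(x$s, x$f, 1) +
    local({
      st <- stub_vector(x$s, x$f, 1)
      m <- outer(st, st) / sum(st)
      diag(m) <- diag(m) / 2
      m
    })
  expect_lt(max(abs(g1 - general)), 1e-10)
  off <- outer(fn, fn) * (x$s$n_nodes * x$s$mean_k - 2 * alpha)
  expect_equal(g1[1, 2], off[1, 2], tolerance = 1e-12)
})

test_that("predictions approach the q = 0 closed forms as q -> 0", {
  x <- make_pred_inputs()
  q_small <- 1e-3
  phi_lim <- predict_populations(x$s, x$f, 0, v0 = x$v0)
  phi_near <- predict_populations(x$s, x$f, q_small, omega = x$omega(q_small))
  expect_lt(max(abs(phi_near - phi_lim)), 1e-2 * x$s$n_nodes)

  gm_lim <- predict_embedded(x$s, x$f, 0, v0 = x$v0)
  gm_near <- predict_embedded(x$s, x$f, q_small, omega = x$omega(q_small))
  expect_lt(max(abs(gm_near - gm_lim)), 1e-2 * x$s$n_nodes)
})

test_that("the self-loop share of the prediction is nondecreasing in q", {
  x <- make_pred_inputs()
  shares <- vapply(seq(0, 1, 0.1), function(q) {
    self_loop_share(embedding_prediction(x$s, x$b, x$f, q))
  }, 0)
  expect_true(all(diff(shares) >= -1e-12))
})

test_that("the one-stop constructor wires everything together", {
  x <- make_pred_inputs()
  pred <- embedding_prediction(x$a, x$b, x$f, 0.5)
  expect_s3_class(pred, "embedding_prediction")
  expect_equal(pred$provenance, "general-q")
  expect_equal(sum(pred$phi_mean), x$s$n_nodes, tolerance = 1e-6)
  expect_equal(embedding_prediction(x$s, x$b, x$f, 1)$provenance, "q=1")
  expect_equal(embedding_prediction(x$s, x$b, x$f, 0)$provenance, "q=0")
  tt <- tidy(pred)
  expect_named(tt, c("node", "f", "phi_mean", "self_loop_weight", "stubs"))
  expect_equal(nrow(tt), 10)
})
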