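#' Expected realized populations
#'
#' Mean number of A-nodes landing on each location node. For `q` in (0, 1)
#' this is `f * delta(q) + q * alpha * Omega(q) f`: sources contribute
#' their target draw, walkers contribute the discounted propagator mass.
#' At `q = 1` the walk never moves and the populations collapse to
#' `N_A * f`; in the `q = 0` limit the `alpha` walker-placed nodes follow
#' the stationary distribution, `f (N_A - alpha) + alpha v0`.
#'
#' @param summaries [moment_summaries()] of network A's trajectory.
#' @param f Attractiveness weights on B.
#' @param q Stopping probability in `[0, 1]`.
#' @param omega Walk propagator from [walk_propagator()]; required for
#'   `q` in (0, 1).
#' @param v0 Stationary distribution; required for `q = 0`.
#' @return Numeric vector of expected populations summing to `N_A`.
#' @export
predict_populations <- function(summaries, f, q, omega = NULL, v0 = NULL) {
  check_prediction_inputs(summaries, f, q, omega, v0)
  f <- as.numeric(as_attractiveness(f))
  n_a <- summaries$n_nodes
  alpha <- summaries$alpha
  if (q == 1) {
    n_a * f
  } else if (q == 0) {
    f * (n_a - alpha) + alpha * v0
  } else {
    f * delta_q(summaries, q) + q * alpha * as.numeric(omega %*% f)
  }
}

#' Expected synchronous adjacency
#'
#' Contribution to the embedded network from edges whose endpoints were
#' placed in the same step (a source and one of its neighbors), so their
#' locations are linked by one stopped walk. With `omega_w[i, j] =
#' f[j] Omega(q)[i, j]`, the matrix is `q alpha (f_i delta_ij +
#' (omega_w + t(omega_w))_ij (1 - delta_ij / 2))` for `q > 0` and
#' `alpha (f_i v0_j + f_j v0_i)(1 - delta_ij / 2)` in the `q = 0` limit.
#' Its total mass (upper triangle plus diagonal) is `alpha`, the expected
#' number of walk-placed nodes, for every `q`.
#'
#' @inheritParams predict_populations
#' @return Symmetric nonnegative matrix; diagonal counts within-location
#'   synchronous edges once.
#' @export
synchronous_matrix <- function(summaries, f, q, omega = NULL, v0 = NULL) {
  check_prediction_inputs(summaries, f, q, omega, v0)
  f <- as.numeric(as_attractiveness(f))
  alpha <- summaries$alpha
  n <- length(f)
  if (q == 0) {
    m <- outer(f, v0)
    psi <- alpha * (m + t(m))
    diag(psi) <- alpha * f * v0
  } else {
    if (q == 1) {
      omega <- matrix(0, n, n)
    }
    omega_w <- sweep(omega, 2, f, "*")
    psi <- q * alpha * (diag(f, n) + omega_w + t(omega_w))
    diag(psi) <- q * alpha * (f + diag(omega_w))
  }
  psi
}

#' Expected stub counts for asynchronous pairing
#'
#' Edges whose endpoints were placed in different steps are uncorrelated;
#' each endpoint leaves a "stub" at its location, and stubs are paired at
#' random. The expected stub count per location is
#' `(q beta + gamma) f + q beta Omega(q) f` for `q > 0` and
#' `gamma f + beta v0` in the `q = 0` limit; its total is `beta + gamma`
#' for every `q`.
#'
#' @inheritParams predict_populations
#' @return Nonnegative numeric vector of expected stub counts.
#' @export
stub_vector <- function(summaries, f, q, omega = NULL, v0 = NULL) {
  check_prediction_inputs(summaries, f, q, omega, v0)
  f <- as.numeric(as_attractiveness(f))
  beta <- summaries$beta
  gamma <- summaries$gamma
  if (q == 0) {
    gamma * f + beta * v0
  } else if (q == 1) {
    (beta + gamma) * f
  } else {
    (q * beta + gamma) * f + q * beta * as.numeric(omega %*% f)
  }
}

#' Expected embedded adjacency
#'
#' Sum of the synchronous contribution and the random stub pairing:
#' `<Gamma_ij> = psi_ij + (phi_i phi_j / sum_l phi_l)(1 - delta_ij / 2)`,
#' with `phi` the stub vector. At `q = 1` the closed form
#' `f_i alpha delta_ij + f_i f_j (N_A <k>_A - 2 alpha)(1 - delta_ij / 2)`
#' is used and verified against the general assembly to 1e-10. The total
#' mass is `N_A <k>_A / 2 = |E_A|` in expectation for every `q`.
#'
#' @inheritParams predict_populations
#' @return Symmetric nonnegative matrix of expected edge weights.
#' @export
predict_embedded <- function(summaries, f, q, omega = NULL, v0 = NULL) {
  check_prediction_inputs(summaries, f, q, omega, v0)
  fn <- as.numeric(as_attractiveness(f))
  psi <- synchronous_matrix(summaries, f, q, omega = omega, v0 = v0)
  stubs <- stub_vector(summaries, f, q, omega = omega, v0 = v0)
  gamma_mean <- psi + stub_pairing(stubs, psi)
  if (q == 1) {
    n_a <- summaries$n_nodes
    alpha <- summaries$alpha
    direct <- outer(fn, fn) * (n_a * summaries$mean_k - 2 * alpha)
    diag(direct) <- diag(direct) / 2 + alpha * fn
    if (max(abs(direct - gamma_mean)) > 1e-10) {
      abort("q = 1 closed form disagrees with the general assembly")
    }
    gamma_mean <- direct
  }
  gamma_mean
}

stub_pairing <- function(stubs, psi) {
  total <- sum(stubs)
  n <- length(stubs)
  if (total <= 0) {
    if (sum(psi) > 1e-12 && total < 0) {
      abort("negative stub mass is inconsistent with a nonzero synchronous part")
    }
    return(matrix(0, n, n))
  }
  pair <- outer(stubs, stubs) / total
  diag(pair) <- diag(pair) / 2
  pair
}

check_prediction_inputs <- function(summaries, f, q, omega, v0) {
  if (!inherits(summaries, "embedding_summaries")) {
    abort("summaries must come from moment_summaries()")
  }
  if (!(length(q) == 1 && q >= 0 && q <= 1)) abort("q must lie in [0, 1]")
  n <- length(as_attractiveness(f))
  if (q == 0) {
    if (is.null(v0)) abort("q = 0 predictions need the stationary distribution v0")
    if (length(v0) != n) abort("v0 and f have mismatched lengths")
  } else if (q < 1) {
    if (is.null(omega)) abort("0 < q < 1 predictions need the walk propagator omega")
    if (!is.matrix(omega) || any(dim(omega) != n)) {
      abort("omega must be an n x n matrix matching f")
    }
  }
  invisible(TRUE)
}

#' Assemble the full analytic prediction for one q
#'
#' One-stop constructor: integrates the moment equations for network A's
#' degree moments (unless ready-made summaries are given), builds the
#' spectral objects for B, and returns expected populations and the
#' expected embedded adjacency.
#'
#' @param moments [degree_moments()] of network A, an igraph to summarize,
#'   or ready-made `"embedding_summaries"`.
#' @param graph_b Location network B.
#' @param f Attractiveness weights on B.
#' @param q Stopping probability in `[0, 1]`.
#' @param step RK4 step for the moment integration (ignored when summaries
#'   are supplied).
#' @return An `"embedding_prediction"`: list with `phi_mean`, `gamma_mean`,
#'   `psi`, `stubs`, `q`, `provenance` (`"general-q"`, `"q=1"`, `"q=0"`),
#'   `summaries`, `f`.
#' @examples
#' b <- generate_path(5)
#' f <- sample_attractiveness(5, seed = 1)
#' a <- generate_er(200, 0.03, seed = 2)
#' pred <- embedding_prediction(a, b, f, q = 0.5)
#' sum(pred$phi_mean) # N_A
#' @export
embedding_prediction <- function(moments, graph_b, f, q, step = 0.1) {
  if (inherits(moments, "embedding_summaries")) {
    summaries <- moments
  } else {
    summaries <- moment_summaries(integrate_moments(moments, step = step))
  }
  f <- as_attractiveness(f)
  if (length(f) != igraph::vcount(graph_b)) {
    abort("length(f) must match the nodes of B")
  }
  omega <- NULL
  v0 <- NULL
  if (q == 0) {
    v0 <- stationary_distribution(transition_matrix(graph_b, f))
  } else if (q < 1) {
    omega <- walk_propagator(transition_matrix(graph_b, f), q)
  }
  structure(
    list(
      phi_mean = predict_populations(summaries, f, q, omega = omega, v0 = v0),
      gamma_mean = predict_embedded(summaries, f, q, omega = omega, v0 = v0),
      psi = synchronous_matrix(summaries, f, q, omega = omega, v0 = v0),
      stubs = stub_vector(summaries, f, q, omega = omega, v0 = v0),
      q = q,
      provenance = if (q == 1) "q=1" else if (q == 0) "q=0" else "general-q",
      summaries = summaries,
      f = f
    ),
    class = "embedding_prediction"
  )
}

#' @export
print.embedding_prediction <- function(x, ...) {
  cat(sprintf(
    "<embedding_prediction> q = %g (%s), N_A = %d over %d locations; self-loop share %.3f\n",
    x$q, x$provenance, x$summaries$n_nodes, length(x$phi_mean), self_loop_share(x$gamma_mean)
  ))
  invisible(x)
}

#' Self-loop weight share of an embedded adjacency
#'
#' Fraction of total edge mass sitting on the diagonal (within-location
#' edges): the natural scalar measure of how local an embedding is, and a
#' nondecreasing function of `q` for the analytic prediction.
#'
#' @param gamma A symmetric embedded adjacency (simulated or predicted).
#' @return A number in `[0, 1]`.
#' @export
self_loop_share <- function(gamma) {
  if (inherits(gamma, "embedding_prediction")) gamma <- gamma$gamma_mean
  if (inherits(gamma, "embedding_realization")) gamma <- gamma$gamma
  total <- sum(gamma[upper.tri(gamma)]) + sum(diag(gamma))
  if (total == 0) {
    return(NA_real_)
  }
  sum(diag(gamma)) / total
}
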