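#' Simulate an ensemble of embeddings
#'
#' Runs `n_realizations` independent embeddings and accumulates entrywise
#' means and standard errors of the realized populations and the embedded
#' adjacency. Network A can be fixed (all realizations share it, only the
#' embedding randomness varies) or regenerated per realization by passing
#' `a_generator`, matching experiments that average over the A-ensemble as
#' well; in that case the returned degree moments are the across-run
#' average.
#'
#' @param graph_a Network A, or `NULL` when `a_generator` is given.
#' @param graph_b Location network B.
#' @param f Attractiveness weights on B.
#' @param q Stopping probability in `[0, 1]`.
#' @param n_realizations Number of independent runs (>= 1).
#' @param seed Optional base seed; realization `i` uses `seed + i - 1`, so
#'   ensembles are reproducible and individual runs replayable.
#' @param a_generator Optional `function(seed)` returning a fresh igraph
#'   for network A.
#' @param trace Keep per-run moment traces (see [run_embedding()]).
#' @return An `"embedding_ensemble"`: means/SEs for `phi` and `gamma`,
#'   averaged `moments`, run metadata, and `traces` (list or `NULL`).
#' @export
run_ensemble <- function(graph_a, graph_b, f, q, n_realizations,
                         seed = NULL, a_generator = NULL, trace = FALSE) {
  if (n_realizations < 1) abort("n_realizations must be >= 1")
  if (is.null(graph_a) && is.null(a_generator)) {
    abort("provide graph_a or a_generator")
  }
  f <- as_attractiveness(f)
  n_b <- igraph::vcount(graph_b)
  phi_sum <- numeric(n_b)
  phi_sq <- numeric(n_b)
  gam_sum <- matrix(0, n_b, n_b)
  gam_sq <- matrix(0, n_b, n_b)
  k_sum <- 0
  k2_sum <- 0
  edges_sum <- 0
  traces <- if (isTRUE(trace)) vector("list", n_realizations) else NULL
  n_a <- NULL
  for (i in seq_len(n_realizations)) {
    run_seed <- if (is.null(seed)) NULL else seed + i - 1
    a_i <- if (is.null(a_generator)) {
      graph_a
    } else {
      a_generator(if (is.null(run_seed)) NULL else run_seed + 500000L)
    }
    if (is.null(n_a)) n_a <- igraph::vcount(a_i)
    mom <- degree_moments(a_i)
    k_sum <- k_sum + mom$mean_k
    k2_sum <- k2_sum + mom$mean_k2
    edges_sum <- edges_sum + igraph::ecount(a_i)
    real <- run_embedding(a_i, graph_b, f, q, seed = run_seed, trace = trace)
    phi_sum <- phi_sum + real$phi
    phi_sq <- phi_sq + real$phi^2
    gam_sum <- gam_sum + real$gamma
    gam_sq <- gam_sq + real$gamma^2
    if (isTRUE(trace)) traces[[i]] <- real$trace
  }
  n <- n_realizations
  se_from <- function(s, s2) {
    if (n < 2) {
      return(s * NA_real_)
    }
    v <- (s2 - s^2 / n) / (n - 1)
    v[v < 0] <- 0
    sqrt(v / n)
  }
  structure(
    list(
      n = n,
      q = q,
      n_a = n_a,
      n_b = n_b,
      mean_edges_a = edges_sum / n,
      phi_mean = phi_sum / n,
      phi_se = se_from(phi_sum, phi_sq),
      gamma_mean = gam_sum / n,
      gamma_se = se_from(gam_sum, gam_sq),
      moments = as_degree_moments(n_a, k_sum / n, k2_sum / n),
      regenerated_a = !is.null(a_generator),
      seed = seed,
      f = f,
      traces = traces
    ),
    class = "embedding_ensemble"
  )
}

#' @export
print.embedding_ensemble <- function(x, ...) {
  cat(sprintf(
    "<embedding_ensemble> %d runs, q = %g, N_A = %d -> N_B = %d (%s network A)\n",
    x$n, x$q, x$n_a, x$n_b, if (x$regenerated_a) "regenerated" else "fixed"
  ))
  invisible(x)
}

#' Ensemble moment traces at chosen times
#'
#' Averages the per-run empirical moment traces of the unassigned pool at
#' the requested integer step counts, for comparison against the
#' mean-field trajectory. Runs that finished before a requested time are
#' excluded at that time.
#'
#' @param traces List of trace tibbles from traced runs.
#' @param at Integer vector of step counts.
#' @return A tibble with one row per time: mean and SE of `eta`, `k1`,
#'   `k2`, `kd` plus the number of contributing runs.
#' @export
summarize_traces <- function(traces, at) {
  if (length(traces) == 0) abort("no traces supplied")
  purrr::map_dfr(at, function(t0) {
    vals <- purrr::map(traces, function(tr) {
      row <- tr[tr$t == t0 & tr$eta > 0, , drop = FALSE]
      if (nrow(row) == 1) as.numeric(row[1, c("eta", "k1", "k2", "kd")]) else NULL
    })
    vals <- do.call(rbind, vals[!vapply(vals, is.null, TRUE)])
    if (is.null(vals) || nrow(vals) == 0) {
      return(tibble(
        t = t0, n_runs = 0L,
        eta_mean = NA_real_, eta_se = NA_real_, k1_mean = NA_real_, k1_se = NA_real_,
        k2_mean = NA_real_, k2_se = NA_real_, kd_mean = NA_real_, kd_se = NA_real_
      ))
    }
    m <- colMeans(vals)
    se <- apply(vals, 2, sd) / sqrt(nrow(vals))
    tibble(
      t = t0, n_runs = nrow(vals),
      eta_mean = m[1], eta_se = se[1], k1_mean = m[2], k1_se = se[2],
      k2_mean = m[3], k2_se = se[3], kd_mean = m[4], kd_se = se[4]
    )
  })
}

#' Compare ensemble means with an analytic prediction
#'
#' Entrywise z-scores `(simulated mean - predicted) / SE` for the realized
#' populations and the embedded adjacency (upper triangle plus diagonal,
#' self-loops flagged). Entries that cannot support a z-score are excluded
#' from the summary fractions and labeled: `structural_zero` when
#' simulation and prediction are both exactly zero, `degenerate_se` when
#' the simulated SE is zero (typically tiny-weight cells never hit at this
#' ensemble size).
#'
#' @param ensemble An [run_ensemble()] result.
#' @param prediction An [embedding_prediction()] for the same `q` and B.
#' @return An `"embedding_comparison"` with tibbles `phi` and `gamma`;
#'   [glance()] gives the `|z| < 3` fractions.
#' @export
compare_tables <- function(ensemble, prediction) {
  if (!inherits(ensemble, "embedding_ensemble")) abort("ensemble must be an embedding_ensemble")
  if (!inherits(prediction, "embedding_prediction")) abort("prediction must be an embedding_prediction")
  if (length(ensemble$phi_mean) != length(prediction$phi_mean)) {
    abort("ensemble and prediction have mismatched numbers of locations")
  }
  if (!isTRUE(all.equal(ensemble$q, prediction$q))) {
    abort("ensemble and prediction were produced for different q")
  }
  phi <- tibble(
    node = seq_along(ensemble$phi_mean),
    sim_mean = ensemble$phi_mean,
    sim_se = ensemble$phi_se,
    predicted = prediction$phi_mean
  )
  n_b <- ensemble$n_b
  idx <- which(upper.tri(matrix(0, n_b, n_b), diag = TRUE), arr.ind = TRUE)
  gamma <- tibble(
    i = idx[, 1],
    j = idx[, 2],
    self_loop = idx[, 1] == idx[, 2],
    sim_mean = ensemble$gamma_mean[idx],
    sim_se = ensemble$gamma_se[idx],
    predicted = prediction$gamma_mean[idx]
  )
  classify <- function(df) {
    df |>
      dplyr::mutate(
        excluded = dplyr::case_when(
          .data$sim_mean == 0 & .data$sim_se == 0 & .data$predicted == 0 ~ "structural_zero",
          .data$sim_se == 0 | is.na(.data$sim_se) ~ "degenerate_se",
          TRUE ~ NA_character_
        ),
        z = dplyr::if_else(
          is.na(.data$excluded),
          (.data$sim_mean - .data$predicted) / .data$sim_se,
          NA_real_
        )
      )
  }
  structure(
    list(
      phi = classify(phi),
      gamma = classify(gamma),
      q = ensemble$q,
      n_realizations = ensemble$n,
      provenance = prediction$provenance
    ),
    class = "embedding_comparison"
  )
}

#' @export
print.embedding_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0(
      "<embedding_comparison> q = %g (%s), %d runs\n",
      "  populations: %d entries, |z|<3 fraction %.3f (%d excluded)\n",
      "  edge weights: %d entries, |z|<3 fraction %.3f (%d excluded)\n"
    ),
    x$q, x$provenance, x$n_realizations,
    nrow(x$phi), g$frac_phi_z_lt3, g$n_excluded_phi,
    nrow(x$gamma), g$frac_gamma_z_lt3, g$n_excluded_gamma
  ))
  invisible(x)
}
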