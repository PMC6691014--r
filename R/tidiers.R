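#' Tidy methods for flexembed objects
#'
#' Broom-style accessors. `tidy()` returns one row per elementary unit
#' (location node, trajectory time point, comparison entry); `glance()`
#' returns a one-row summary.
#'
#' @param x A flexembed object.
#' @param ... Unused.
#' @return A tibble.
#' @name flexembed-tidiers
NULL

#' @rdname flexembed-tidiers
#' @method tidy embedding_realization
#' @export
tidy.embedding_realization <- function(x, ...) {
  tibble(
    node = seq_along(x$phi),
    phi = x$phi,
    self_loop_weight = diag(x$gamma),
    strength = rowSums(x$gamma) + diag(x$gamma)
  )
}

#' @rdname flexembed-tidiers
#' @method glance embedding_realization
#' @export
glance.embedding_realization <- function(x, ...) {
  tibble(
    n_a = x$n_a, n_b = x$n_b, q = x$q, n_steps = x$n_steps,
    n_edges_a = x$n_edges_a,
    self_loop_share = self_loop_share(x$gamma)
  )
}

#' @rdname flexembed-tidiers
#' @method tidy embedding_prediction
#' @export
tidy.embedding_prediction <- function(x, ...) {
  tibble(
    node = seq_along(x$phi_mean),
    f = as.numeric(x$f),
    phi_mean = x$phi_mean,
    self_loop_weight = diag(x$gamma_mean),
    stubs = x$stubs
  )
}

#' @rdname flexembed-tidiers
#' @method glance embedding_prediction
#' @export
glance.embedding_prediction <- function(x, ...) {
  tibble(
    q = x$q, provenance = x$provenance,
    n_a = x$summaries$n_nodes, n_b = length(x$phi_mean),
    total_phi = sum(x$phi_mean),
    total_weight = sum(x$gamma_mean[upper.tri(x$gamma_mean)]) + sum(diag(x$gamma_mean)),
    self_loop_share = self_loop_share(x$gamma_mean)
  )
}

#' @rdname flexembed-tidiers
#' @method tidy moment_trajectory
#' @export
tidy.moment_trajectory <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("eta", "k1", "k2", "kd"), names_to = "moment", values_to = "value")
}

#' @rdname flexembed-tidiers
#' @method glance embedding_summaries
#' @export
glance.embedding_summaries <- function(x, ...) {
  tibble(
    n_a = x$n_nodes, mean_k = x$mean_k, mean_k2 = x$mean_k2,
    t_star = x$t_star, alpha = x$alpha, beta = x$beta,
    gamma = x$gamma, gamma_quad = x$gamma_quad
  )
}

#' @rdname flexembed-tidiers
#' @method tidy embedding_comparison
#' @export
tidy.embedding_comparison <- function(x, ...) {
  dplyr::bind_rows(
    x$phi |>
      dplyr::transmute(
        component = "phi",
        entry = sprintf("phi_%d", .data$node),
        self_loop = FALSE,
        .data$sim_mean, .data$sim_se, .data$predicted, .data$z, .data$excluded
      ),
    x$gamma |>
      dplyr::transmute(
        component = "gamma",
        entry = sprintf("gamma_%d_%d", .data$i, .data$j),
        self_loop = .data$self_loop,
        .data$sim_mean, .data$sim_se, .data$predicted, .data$z, .data$excluded
      )
  )
}

#' @rdname flexembed-tidiers
#' @method glance embedding_comparison
#' @export
glance.embedding_comparison <- function(x, ...) {
  frac <- function(df) {
    z <- df$z[is.na(df$excluded)]
    if (length(z) == 0) NA_real_ else mean(abs(z) < 3)
  }
  tibble(
    q = x$q,
    n_realizations = x$n_realizations,
    frac_phi_z_lt3 = frac(x$phi),
    frac_gamma_z_lt3 = frac(x$gamma),
    n_excluded_phi = sum(!is.na(x$phi$excluded)),
    n_excluded_gamma = sum(!is.na(x$gamma$excluded))
  )
}
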