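#' Plot a moment trajectory
#'
#' Mean-field evolution of the unassigned pool: `eta / N_A` together with
#' the neighbor-count moments `k1`, `k2`, `kd` against continuous time,
#' with the completion time `t*` marked.
#'
#' @param object A `"moment_trajectory"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot moment_trajectory
#' @export
autoplot.moment_trajectory <- function(object, ...) {
  n_a <- attr(object, "moments")$n_nodes
  df <- as_tibble(object) |>
    dplyr::mutate(eta = .data$eta / n_a) |>
    tidyr::pivot_longer(c("eta", "k1", "k2", "kd"),
      names_to = "moment", values_to = "value"
    ) |>
    dplyr::mutate(moment = factor(.data$moment,
      levels = c("eta", "k1", "k2", "kd"),
      labels = c("unassigned fraction", "<k> unassigned", "<k2> unassigned", "<k> assigned")
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "t_star"), linetype = "dashed") +
    ggplot2::facet_wrap(~moment, scales = "free_y") +
    ggplot2::labs(x = "time (source selections)", y = NULL)
}

#' Plot a simulation-versus-theory comparison
#'
#' Simulated ensemble means against analytic predictions for realized
#' populations and embedded edge weights (self-loops highlighted), with
#' the identity line; well-matched theory puts everything on the
#' diagonal.
#'
#' @param object An `"embedding_comparison"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot embedding_comparison
#' @export
autoplot.embedding_comparison <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(is.na(.data$excluded)) |>
    dplyr::mutate(component = factor(.data$component,
      levels = c("phi", "gamma"),
      labels = c("realized populations", "embedded edge weights")
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$sim_mean, color = .data$self_loop)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red"), name = "self-loop") +
    ggplot2::labs(
      x = "analytic prediction", y = "simulated ensemble mean",
      title = sprintf("q = %g, %d realizations", object$q, object$n_realizations)
    )
}

#' Plot one embedding realization
#'
#' Realized populations against attractiveness; under the fully local
#' rule (`q = 1`) the points scatter around the line `N_A * f`.
#'
#' @param object An `"embedding_realization"`.
#' @param f Attractiveness weights used in the run.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot embedding_realization
#' @export
autoplot.embedding_realization <- function(object, f, ...) {
  df <- tibble(
    f = as.numeric(as_attractiveness(f)),
    phi = object$phi
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$phi)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$n_a, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "attractiveness f", y = "realized population",
      title = sprintf("one realization, q = %g", object$q)
    )
}
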