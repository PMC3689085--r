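#' Plot recognition accuracy across testing cycles
#'
#' Per-cycle and cumulative mean RA curves, the standard way to display a
#' classifier's behaviour over a testing session (the cumulative value at
#' the last cycle is the overall RA).
#'
#' @param object An `emg_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emg_eval
#' @export
autoplot.emg_eval <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("ra", "cumulative_ra"), names_to = "series",
                        values_to = "value") |>
    dplyr::mutate(series = ifelse(.data$series == "ra",
                                  "per-cycle", "cumulative mean"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cycle, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "testing cycle", y = "recognition accuracy (%)",
                  colour = NULL,
                  title = sprintf("%s + %s", object$method,
                                  toupper(object$feature_kind))) +
    ggplot2::theme_minimal()
}

#' Plot a method comparison across simulated subjects
#'
#' One point per subject and method, grouped by feature kind.
#'
#' @param object An `emg_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emg_comparison
#' @export
autoplot.emg_comparison <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$method, .data$overall_ra,
                               colour = factor(.data$subject))) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "black", linewidth = 0.3) +
    ggplot2::facet_wrap(~feature_kind, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "overall recognition accuracy (%)",
                  colour = "subject") +
    ggplot2::theme_minimal()
}

#' Plot classifier-parameter drift diagnostics
#'
#' Mean-vector and principal-axis cosines against the training model, per
#' class, across testing cycles.
#'
#' @param diagnostics A tibble from [drift_diagnostics()].
#' @return A ggplot object.
#' @export
plot_drift_diagnostics <- function(diagnostics) {
  df <- diagnostics |>
    tidyr::pivot_longer(c("mean_cos", "axis1_cos", "axis2_cos"),
                        names_to = "quantity", values_to = "cosine") |>
    dplyr::filter(is.finite(.data$cosine))
  ggplot2::ggplot(df, ggplot2::aes(.data$cycle, .data$cosine,
                                   colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = "testing cycle",
                  y = "cosine vs training parameters") +
    ggplot2::theme_minimal()
}
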