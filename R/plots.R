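# ggplot2 helpers for the pipeline's result types.

#' Plot per-window heart-rate estimates
#'
#' @param estimates Output of [estimate_hr()].
#' @param truth Optional tibble `t`, `hr` of ground-truth heart rate
#'   (e.g. from a simulated session).
#' @return A ggplot object.
#' @export
plot_hr_estimates <- function(estimates, truth = NULL) {
  p <- ggplot2::ggplot(estimates,
                       ggplot2::aes(x = .data$window_start_s, y = .data$bpm)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "window start (s)", y = "heart rate (bpm)",
                  shape = "accepted")
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = truth, ggplot2::aes(x = .data$t, y = .data$hr),
      inherit.aes = FALSE, colour = "grey50", linetype = 2)
  }
  p + ggplot2::theme_minimal()
}

#' Plot per-window facial features
#'
#' @param features Output of [aggregate_features()] or
#'   [session_features()].
#' @return A ggplot object (one facet per feature, free y scales).
#' @export
plot_features <- function(features) {
  long <- tidyr::pivot_longer(features,
                              cols = dplyr::any_of(paste0("F", 1:9)),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_start_s,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "window start (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram and density of per-subject accuracies
#'
#' Summarises a cohort evaluation the way such results are usually
#' reported: a histogram of per-subject accuracy with a density overlay
#' and the cohort mean marked.
#'
#' @param object A `cohort_result` (see [evaluate_cohort()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_result <- function(object, ...) {
  d <- dplyr::filter(object$per_subject, !is.na(.data$accuracy))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 10, fill = "grey80", colour = "grey40") +
    ggplot2::geom_density(adjust = 0.25) +
    ggplot2::geom_vline(xintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "per-subject accuracy", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
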