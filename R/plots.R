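# ggplot2 views of trial traces, sessions and cohort performance.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a within-trial trace
#'
#' @param trace A trace tibble from [trial_trace()] (or the result of
#'   `integrate_trial(..., record_trace = TRUE)`).
#' @param units Unit names to show; default the two premotor units.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, units = c("PMC_1", "PMC_2")) {
  if (!is.data.frame(trace)) trace <- trial_trace(trace)
  long <- tidyr::pivot_longer(trace[, c("t_ms", units)], -"t_ms",
                              names_to = "unit", values_to = "activity")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$activity,
                                     colour = .data$unit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "normalized rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot end-of-trial premotor activity and plastic weights of a session
#'
#' Two panels: the trial-by-trial end-of-trial activity of the two
#' premotor units (the choice readout), and the six plastic weights.
#' A vertical line marks the reversal.
#'
#' @param object A `bg_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_session <- function(object, ...) {
  tr <- object$trials
  act <- tr |>
    dplyr::select("trial", "PMC_1", "PMC_2") |>
    tidyr::pivot_longer(-"trial", names_to = "series",
                        values_to = "value") |>
    dplyr::mutate(panel = "end-of-trial PMC activity")
  wts <- tr |>
    dplyr::select("trial", dplyr::all_of(plastic_weight_names())) |>
    tidyr::pivot_longer(-"trial", names_to = "series",
                        values_to = "value") |>
    dplyr::mutate(panel = "plastic weights")
  ggplot2::ggplot(dplyr::bind_rows(act, wts),
                  ggplot2::aes(.data$trial, .data$value,
                               colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$config$reversal_trial,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cohort-mean performance curve
#'
#' @param object A `bg_cohort`.
#' @param window Performance window length in trials.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_cohort <- function(object, window = 25, ...) {
  perf <- cohort_performance(object, window)
  ggplot2::ggplot(perf, ggplot2::aes(.data$window_start,
                                     100 * .data$mean_correct)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = 100 * (.data$mean_correct - .data$sd_correct),
      ymax = 100 * (.data$mean_correct + .data$sd_correct)),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$config$reversal_trial,
                        linetype = "dashed") +
    ggplot2::labs(x = "trial (window start)", y = "% correct") +
    ggplot2::theme_minimal()
}
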