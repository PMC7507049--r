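#' Plot a race-model result
#'
#' Mean probability difference curve (AV CDF minus race bound) with the
#' significant integration window(s) shaded.
#'
#' @param object a `race_model_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.race_model_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$mean_curve,
                       ggplot2::aes(x = .data$t_ms, y = .data$mean_diff))
  if (nrow(object$windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$peak_latency_ms,
                      y = object$peak_benefit, shape = 1, size = 3) +
    ggplot2::labs(x = "Time (ms)", y = "P(AV) - P(race)",
                  title = "Race-model probability difference",
                  subtitle = sprintf("peak benefit %.3f at %g ms, positive AUC %.2f",
                                     object$peak_benefit, object$peak_latency_ms,
                                     object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a pointwise group comparison
#'
#' t statistic per time sample with significant windows shaded.
#'
#' @param object a `group_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  p <- ggplot2::ggplot(object$samples,
                       ggplot2::aes(x = .data$time_ms, y = .data$t))
  if (nrow(object$windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "t statistic",
                  title = sprintf("%s vs %s (%s)", object$groups[1],
                                  object$groups[2], object$tail)) +
    ggplot2::theme_minimal()
}

#' Plot global connectivity time series
#'
#' @param data tibble with `time_ms`, `mean_pli` and optionally `group`
#'   and/or `band` columns (as produced by [global_connectivity()] rows bound
#'   across subjects/conditions).
#' @return a ggplot object.
#' @export
plot_connectivity <- function(data) {
  aes <- ggplot2::aes(x = .data$time_ms, y = .data$mean_pli)
  if ("group" %in% names(data)) {
    aes <- ggplot2::aes(x = .data$time_ms, y = .data$mean_pli,
                        colour = .data$group)
  }
  p <- ggplot2::ggplot(data, aes) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "Time (ms)", y = "Mean PLI",
                  title = "Global functional connectivity") +
    ggplot2::theme_minimal()
  if ("band" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~band, scales = "free_y")
  }
  p
}
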