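# Plotting layer: raster plots, count histograms with Poisson overlays and
# variance-versus-mean scatter. Figures are artifacts; all quantitative
# surfaces are the CSV/JSON outputs.

#' Temporal raster plot of an event series
#'
#' @param series An [event_series()].
#' @return A ggplot object.
#' @export
plot_raster <- function(series) {
  series <- validate_event_series(series)
  df <- data.frame(t = series$times / 60)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$t, y = 0, yend = 1)) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::xlim(0, series$duration / 60) +
    ggplot2::labs(x = "scan time (min)",
                  title = sprintf("%s: %d detections (%.2g events/min)",
                                  series$label, n_events(series),
                                  event_rate(series))) +
    ggplot2::theme_minimal()
}

#' Histogram of window counts with Poisson overlay
#'
#' @param counts An [count_in_windows()] result.
#' @param poisson_overlay Overlay the Poisson pmf at the scan mean.
#' @return A ggplot object.
#' @export
plot_count_histogram <- function(counts, poisson_overlay = TRUE) {
  h <- count_histogram(counts)
  h$fraction <- h$frequency / sum(h$frequency)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$count, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "events per window", y = "fraction of windows",
                  title = sprintf("%s, %g s windows", counts$source_label,
                                  counts$spec$window)) +
    ggplot2::theme_minimal()
  lam <- scan_mean(counts)
  if (poisson_overlay && lam > 0) {
    ref <- poisson_reference_pmf(lam, max(h$count))
    p <- p + ggplot2::geom_line(
      data = data.frame(count = ref$k, fraction = ref$prob),
      ggplot2::aes(x = .data$count, y = .data$fraction), linetype = 2)
  }
  p
}

#' Variance-versus-mean scatter with zero-intercept fit
#'
#' Points above the dashed 1:1 line are overdispersed relative to Poisson.
#'
#' @param points Data frame with columns `mean`, `variance` and optionally
#'   `kind`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_variance_mean <- function(points, title = NULL) {
  slope <- zero_intercept_fit(points)
  aes <- if ("kind" %in% names(points)) {
    ggplot2::aes(x = .data$mean, y = .data$variance, colour = .data$kind)
  } else {
    ggplot2::aes(x = .data$mean, y = .data$variance)
  }
  ggplot2::ggplot(points, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = slope, intercept = 0) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean events per window", y = "variance",
                  title = title %||% sprintf("zero-intercept slope %.2f",
                                             slope)) +
    ggplot2::theme_minimal()
}
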