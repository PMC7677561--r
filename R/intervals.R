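# Window counting: convert an event stream into equivalent-blood-sample
# counts, detection fractions and count histograms.

#' Count events in a family of windows
#'
#' Lays windows `[t, t + window)` with starts `t = 0, stride, 2 stride, ...`
#' over the scan (while `t + window <= duration`; trailing partial windows are
#' discarded) and tallies the events in each. The half-open convention means
#' an event exactly at `t + window` belongs to the next window, so in
#' nonoverlapping mode the counts conserve the total event count over the
#' covered span.
#'
#' @param series An [event_series()].
#' @param spec An [interval_spec()]; `spec$window` must not exceed the scan
#'   duration.
#' @return An object of class `interval_counts` with fields `spec`, `starts`,
#'   `counts` and `source_label`.
#' @examples
#' s <- event_series(c(10, 70, 130), 180)
#' count_in_windows(s, interval_spec(60, mode = "nonoverlapping"))$counts
#' @export
count_in_windows <- function(series, spec) {
  series <- validate_event_series(series)
  if (!inherits(spec, "interval_spec")) stop("`spec` must be an interval_spec")
  if (spec$window > series$duration) {
    stop("window length exceeds the scan duration")
  }
  n_win <- floor((series$duration - spec$window) / spec$stride + 1e-9) + 1
  starts <- (seq_len(n_win) - 1) * spec$stride
  # events in [t, t+w): (# times < t+w) - (# times < t)
  lo <- findInterval(starts, series$times, left.open = TRUE)
  hi <- findInterval(starts + spec$window, series$times, left.open = TRUE)
  structure(list(spec = spec, starts = starts, counts = as.integer(hi - lo),
                 source_label = series$label),
            class = "interval_counts")
}

#' @export
print.interval_counts <- function(x, ...) {
  cat(sprintf(
    "<interval_counts> '%s': %d %s windows of %.0f s (stride %.0f s), mean %.3g\n",
    x$source_label, length(x$counts), x$spec$mode, x$spec$window,
    x$spec$stride, mean(x$counts)))
  invisible(x)
}

stopifnot_windows <- function(counts) {
  if (!inherits(counts, "interval_counts")) {
    stop("`counts` must be an interval_counts object")
  }
  if (length(counts$counts) < 1L) stop("no windows: empty interval_counts")
}

#' Fraction of windows with at least one detection
#'
#' @param counts An [count_in_windows()] result with at least one window.
#' @return Fraction in `[0, 1]`.
#' @export
detection_fraction <- function(counts) {
  stopifnot_windows(counts)
  mean(counts$counts >= 1L)
}

#' Expected detection fraction under a homogeneous Poisson model
#'
#' Closed form `1 - exp(-rate * window / 60)`: the probability that a window
#' of `window` seconds contains at least one event of a Poisson stream at
#' `rate` events per minute. The empirical [detection_fraction()] converges to
#' this value as windows accumulate.
#'
#' @param rate Detection rate in events per minute, non-negative.
#' @param window Window length in seconds, positive.
#' @return Probability in `[0, 1]`.
#' @export
expected_detection_fraction <- function(rate, window) {
  if (any(rate < 0)) stop("`rate` must be non-negative")
  if (any(window <= 0)) stop("`window` must be positive")
  1 - exp(-rate * window / 60)
}

#' Histogram of window counts
#'
#' @param counts An [count_in_windows()] result with at least one window.
#' @return A data frame with columns `count` (0 .. max observed) and
#'   `frequency`; frequencies sum to the number of windows.
#' @export
count_histogram <- function(counts) {
  stopifnot_windows(counts)
  k <- 0:max(counts$counts)
  data.frame(count = k,
             frequency = as.integer(tabulate(counts$counts + 1L,
                                             nbins = length(k))))
}

#' Scan mean: mean events per window
#'
#' The arithmetic mean of the window counts; this is the lambda against which
#' the deviation-from-scan-mean statistic ([dfsm()]) is computed.
#'
#' @param counts An [count_in_windows()] result with at least one window.
#' @return Non-negative mean count per window.
#' @export
scan_mean <- function(counts) {
  stopifnot_windows(counts)
  mean(counts$counts)
}

#' Scan inclusion filter
#'
#' Cohort definitions used when assembling scans for analysis:
#' `"any_detection"` keeps scans with at least one event; `"min_rate"` keeps
#' scans whose overall detection rate strictly exceeds `min_rate` events per
#' minute (default 0.5, the abundant-CTC cohort cutoff).
#'
#' @param series An [event_series()].
#' @param rule `"any_detection"` or `"min_rate"`.
#' @param min_rate Rate threshold in events per minute for `"min_rate"`.
#' @return `TRUE` if the scan passes the rule.
#' @export
inclusion_filter <- function(series, rule = c("any_detection", "min_rate"),
                             min_rate = 0.5) {
  rule <- match.arg(rule)
  series <- validate_event_series(series)
  switch(rule,
         any_detection = n_events(series) >= 1L,
         min_rate = event_rate(series) > min_rate)
}
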