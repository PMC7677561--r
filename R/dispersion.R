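# Statistical core: the deviation-from-scan-mean (DFSM) statistic, Poisson
# reference distributions, variance-versus-mean overdispersion analysis,
# max/min rate ratios and the two-sample KS comparison.

#' Deviation from the scan mean (DFSM)
#'
#' For each window count `C_i` and scan mean `lambda`, the percentage
#' deviation `DFSM_i = |C_i - lambda| / lambda * 100`. A DFSM of 0 means the
#' window reproduced the scan mean exactly; 100 means the count was off by the
#' whole mean (e.g. a zero count). Undefined for `lambda <= 0`.
#'
#' @param counts An [count_in_windows()] result.
#' @param lambda Mean events per window; defaults to [scan_mean()] of
#'   `counts`. Must be strictly positive.
#' @param thresholds DFSM thresholds (percent) summarised in the result
#'   (default 25 and 50).
#' @return An object of class `dfsm_result` with fields `values` (one DFSM
#'   percentage per window), `lambda` and `threshold_fractions` (named
#'   fraction of windows with DFSM at or below each threshold).
#' @examples
#' s <- simulate_homogeneous_poisson(10, 2100, seed = 1)
#' d <- dfsm(count_in_windows(s, interval_spec(120)))
#' d$threshold_fractions
#' @export
dfsm <- function(counts, lambda = NULL, thresholds = c(25, 50)) {
  stopifnot_windows(counts)
  if (is.null(lambda)) lambda <- scan_mean(counts)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("DFSM is undefined for lambda <= 0")
  }
  values <- abs(counts$counts - lambda) / lambda * 100
  tf <- vapply(thresholds, function(th) mean(values <= th), numeric(1))
  names(tf) <- paste0("dfsm", thresholds)
  structure(list(values = values, lambda = lambda, threshold_fractions = tf),
            class = "dfsm_result")
}

#' @export
print.dfsm_result <- function(x, ...) {
  cat(sprintf("<dfsm_result> lambda = %.4g, %d windows; %s\n", x$lambda,
              length(x$values),
              paste(sprintf("%s: %.3f", names(x$threshold_fractions),
                            x$threshold_fractions), collapse = ", ")))
  invisible(x)
}

#' Fraction of windows with DFSM at or below a threshold
#'
#' @param result A [dfsm()] result.
#' @param threshold DFSM threshold in percent, non-negative (inclusive).
#' @return Fraction in `[0, 1]`.
#' @export
dfsm_threshold_fraction <- function(result, threshold) {
  if (!inherits(result, "dfsm_result")) stop("`result` must be a dfsm_result")
  if (threshold < 0) stop("`threshold` must be non-negative (percent)")
  mean(result$values <= threshold)
}

#' Poisson reference probability mass function
#'
#' The count distribution expected under Poisson statistics for a window with
#' mean `lambda`: `P(k) = exp(-lambda) lambda^k / k!` for `k = 0..k_max`, plus
#' the tail mass beyond `k_max` so the reported masses sum to one.
#'
#' @param lambda Mean events per window, non-negative.
#' @param k_max Largest count tabulated explicitly.
#' @return A list with `k` (0..k_max), `prob`, and `tail` (mass above
#'   `k_max`).
#' @export
poisson_reference_pmf <- function(lambda, k_max) {
  if (lambda < 0) stop("`lambda` must be non-negative")
  k <- 0:k_max
  list(k = k, prob = stats::dpois(k, lambda),
       tail = stats::ppois(k_max, lambda, lower.tail = FALSE))
}

#' Expected DFSM threshold fraction under Poisson statistics
#'
#' The probability that a Poisson(`lambda`) count `k` satisfies
#' `|k - lambda| / lambda * 100 <= threshold`, i.e. the Poisson-reference
#' curve against which the empirical DFSM fractions are compared. Computed by
#' enumerating the integers inside the band
#' `[lambda (1 - threshold/100), lambda (1 + threshold/100)]`.
#'
#' @param lambda Mean events per window, strictly positive.
#' @param threshold DFSM threshold in percent, non-negative.
#' @return Expected fraction in `[0, 1]`.
#' @examples
#' poisson_dfsm_fraction(2, 25)  # only k = 2 lies within 25% of 2
#' @export
poisson_dfsm_fraction <- function(lambda, threshold) {
  if (lambda <= 0) stop("expected DFSM fraction is undefined for lambda <= 0")
  if (threshold < 0) stop("`threshold` must be non-negative (percent)")
  klo <- max(0, ceiling(lambda * (1 - threshold / 100) - 1e-9))
  khi <- floor(lambda * (1 + threshold / 100) + 1e-9)
  if (klo > khi) return(0)
  stats::ppois(khi, lambda) - if (klo == 0) 0 else stats::ppois(klo - 1, lambda)
}

#' Monte-Carlo estimate of the Poisson DFSM threshold fraction
#'
#' Simulation route to the same quantity as [poisson_dfsm_fraction()]; the
#' two are cross-checked in the test suite.
#'
#' @param lambda Mean events per window, strictly positive.
#' @param threshold DFSM threshold in percent.
#' @param n Number of simulated counts.
#' @param seed Integer seed or `NULL`.
#' @return Estimated fraction in `[0, 1]`.
#' @export
poisson_dfsm_fraction_mc <- function(lambda, threshold, n = 1e5, seed = NULL) {
  if (lambda <= 0) stop("expected DFSM fraction is undefined for lambda <= 0")
  with_seed(seed, {
    k <- stats::rpois(n, lambda)
    mean(abs(k - lambda) / lambda * 100 <= threshold)
  })
}

#' Finite-scan overlap debias factor for sliding-window variance
#'
#' The sample variance of overlapping sliding-window counts is biased low
#' because the windows share the scan mean: for correlated observations
#' `E[s^2] = sigma^2 (1 - rho_bar)` with `rho_bar` the mean correlation over
#' distinct window pairs. For counts of a homogeneous Poisson process the
#' pairwise correlation is exactly the fractional window overlap
#' `max(0, 1 - lag * stride / window)`, so `rho_bar` follows from the window
#' geometry alone. Dividing the sliding sample variance by the returned
#' factor `1 - rho_bar` makes it unbiased under the Poisson null; under
#' overdispersion the true correlations extend beyond the overlap, so the
#' corrected variance still underestimates and overdispersion detection stays
#' conservative. For nonoverlapping windows the factor is exactly 1.
#'
#' @param n_windows Number of windows (at least 2).
#' @param window Window length in seconds.
#' @param stride Stride between window starts in seconds.
#' @return The factor `1 - rho_bar` in `(0, 1]`.
#' @export
overlap_debias_factor <- function(n_windows, window, stride) {
  if (n_windows < 2L) return(1)
  d <- seq_len(n_windows - 1L)
  rho <- sum(2 * (n_windows - d) * pmax(0, 1 - d * stride / window)) /
    (n_windows * (n_windows - 1))
  1 - rho
}

#' Variance-versus-mean point for one scan and window size
#'
#' Sample mean and sample variance (n - 1 divisor) of the window counts; one
#' point of the variance-versus-mean overdispersion plot. Under Poisson
#' statistics variance equals mean (equidispersion), so points scatter about
#' the 1:1 line; variance above mean indicates a changing underlying rate.
#'
#' @param counts An [count_in_windows()] result with at least 2 windows.
#' @param debias_overlap If `TRUE`, divide the variance by
#'   [overlap_debias_factor()] to remove the finite-scan bias of overlapping
#'   sliding windows. Default `FALSE` (plain sample variance).
#' @return A one-row data frame with columns `mean`, `variance`, `window`,
#'   `stride`, `mode`, `n_windows`, `source_label`.
#' @export
variance_mean_point <- function(counts, debias_overlap = FALSE) {
  stopifnot_windows(counts)
  if (length(counts$counts) < 2L) {
    stop("variance requires at least 2 windows")
  }
  v <- stats::var(counts$counts)
  if (debias_overlap) {
    v <- v / overlap_debias_factor(length(counts$counts), counts$spec$window,
                                   counts$spec$stride)
  }
  data.frame(mean = mean(counts$counts), variance = v,
             window = counts$spec$window, stride = counts$spec$stride,
             mode = counts$spec$mode, n_windows = length(counts$counts),
             source_label = counts$source_label, stringsAsFactors = FALSE)
}

#' Zero-intercept fit of variance against mean
#'
#' Least-squares slope through the origin,
#' `sum(mean_i * variance_i) / sum(mean_i^2)`. A slope of 1 is the Poisson
#' (equidispersion) signature; slopes above 1 indicate overdispersion.
#'
#' @param points A data frame with columns `mean` and `variance` (rows from
#'   [variance_mean_point()]), at least one row with `mean > 0`.
#' @return The fitted slope.
#' @export
zero_intercept_fit <- function(points) {
  if (!is.data.frame(points) || nrow(points) < 1L) {
    stop("`points` must be a non-empty data frame with mean and variance")
  }
  m <- points$mean
  v <- points$variance
  if (all(m == 0)) stop("all means are zero: slope through origin undefined")
  sum(m * v) / sum(m^2)
}

#' Maximum-to-minimum rate ratio
#'
#' Ratio of the largest to the smallest detection rate in a set, the summary
#' used to quantify 24-h (between-scan) variability. When the smallest rate is
#' zero the ratio is undefined; by default `Inf` is returned as the flagged
#' marker, or a positive `floor` may be substituted for zero rates.
#'
#' @param rates Numeric vector of at least 2 non-negative rates.
#' @param floor Optional positive floor substituted for rates below it before
#'   taking the ratio.
#' @return Ratio `>= 1`, or `Inf` when the minimum is zero and no floor is
#'   given.
#' @export
maxmin_rate_ratio <- function(rates, floor = NULL) {
  if (length(rates) < 2L) stop("need at least 2 rates")
  if (any(rates < 0)) stop("rates must be non-negative")
  if (!is.null(floor)) {
    if (floor <= 0) stop("`floor` must be positive")
    rates <- pmax(rates, floor)
  }
  mn <- min(rates)
  if (mn == 0) return(Inf)
  max(rates) / mn
}

#' First-versus-last segment rate ratio of a single scan
#'
#' Splits a scan into its first and last 15-min segments (separated by a 5-min
#' gap), converts the segment counts to rates and returns their max/min ratio.
#' This is the short-timescale analogue of the between-scan 24-h ratio.
#'
#' @param series An [event_series()] of duration at least
#'   `2 * segment + gap` seconds (35 min with the defaults).
#' @param segment Segment length in seconds (default 900).
#' @param gap Gap between the segments in seconds (default 300).
#' @param floor Optional rate floor passed to [maxmin_rate_ratio()].
#' @return Ratio `>= 1`, or `Inf` when one segment is empty.
#' @export
split_scan_ratio <- function(series, segment = 900, gap = 300, floor = NULL) {
  series <- validate_event_series(series)
  need <- 2 * segment + gap
  if (series$duration < need) {
    stop(sprintf("scan shorter than %g s: cannot form both segments", need))
  }
  t <- series$times
  n1 <- sum(t < segment)
  n2 <- sum(t >= segment + gap & t < need)
  maxmin_rate_ratio(c(n1, n2) / segment * 60, floor = floor)
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value
#' (`stats::ks.test(..., exact = FALSE)`). With tied (discrete) data the
#' asymptotic p-value is conservative.
#'
#' @param a,b Non-empty numeric samples.
#' @return A list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                         exact = FALSE))
  list(statistic = unname(res$statistic), p.value = unname(res$p.value))
}
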