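# Independent brute-force oracles used across the suite. Deliberately naive
# O(n*m) implementations, kept separate from the code paths they check.

# Count events in [t, t+w) one window at a time.
brute_window_counts <- function(times, starts, window) {
  vapply(starts, function(t) sum(times >= t & times < t + window), numeric(1))
}

# sup |ECDF_a - ECDF_b| evaluated on the pooled sample points.
brute_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Fraction of DFSM values at or below a threshold, by direct counting.
brute_dfsm_fraction <- function(counts, lambda, threshold) {
  sum(abs(counts - lambda) / lambda * 100 <= threshold) / length(counts)
}

# Variance of a 50/50 mixture of Poisson(mu1) and Poisson(mu2) by pmf mixing
# over a truncated support (independent check of the closed form).
brute_mixture_variance <- function(mu1, mu2, k_max = 500) {
  k <- 0:k_max
  p <- 0.5 * dpois(k, mu1) + 0.5 * dpois(k, mu2)
  m <- sum(k * p)
  sum((k - m)^2 * p)
}

# A small random event series for property tests.
random_series <- function(duration = NULL) {
  duration <- duration %||% runif(1, 30, 300)
  n <- rpois(1, runif(1, 0, 20))
  ctcstream::event_series(sort(runif(n, 0, duration)), duration,
                          label = "random")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
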