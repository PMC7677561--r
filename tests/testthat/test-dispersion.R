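mk_counts <- function(counts, window = 60, stride = window,
                      mode = "nonoverlapping") {
  structure(list(spec = interval_spec(window, stride, mode),
                 starts = (seq_along(counts) - 1) * stride,
                 counts = as.integer(counts), source_label = "toy"),
            class = "interval_counts")
}

test_that("DFSM follows |C - lambda| / lambda * 100", {
  d <- dfsm(mk_counts(c(4, 0, 6, 2)), lambda = 4)
  expect_equal(d$values, c(0, 100, 50, 50))
  expect_error(dfsm(mk_counts(c(0, 0))), "lambda")
  expect_error(dfsm(mk_counts(c(1, 2)), lambda = -1), "lambda")
  # default lambda is the scan mean
  d2 <- dfsm(mk_counts(c(2, 4)))
  expect_equal(d2$lambda, 3)
})

test_that("DFSM threshold fractions are inclusive and match brute force", {
  d <- dfsm(mk_counts(c(4, 0, 6, 2)), lambda = 4)
  expect_equal(dfsm_threshold_fraction(d, 50), 0.75)  # 50% included
  expect_equal(dfsm_threshold_fraction(d, 0), 0.25)
  expect_equal(dfsm_threshold_fraction(d, Inf), 1)
  expect_equal(d$threshold_fractions,
               c(dfsm25 = 0.25, dfsm50 = 0.75))

  set.seed(601)
  for (i in 1:100) {
    counts <- rpois(sample(2:50, 1), runif(1, 0.5, 20))
    lam <- mean(counts)
    if (lam == 0) next
    th <- runif(1, 0, 150)
    expect_equal(dfsm_threshold_fraction(dfsm(mk_counts(counts)), th),
                 brute_dfsm_fraction(counts, lam, th))
  }
})

test_that("Poisson reference pmf is normalised with its tail", {
  ref <- poisson_reference_pmf(0, 5)
  expect_equal(ref$prob, c(1, rep(0, 5)))
  expect_equal(poisson_reference_pmf(1, 0)$prob, exp(-1))
  ref2 <- poisson_reference_pmf(7.3, 12)
  expect_equal(sum(ref2$prob) + ref2$tail, 1, tolerance = 1e-12)
  expect_error(poisson_reference_pmf(-1, 5), "non-negative")
})

test_that("expected Poisson DFSM fraction enumerates the band correctly", {
  # lambda = 2, threshold 25%: only k = 2 lies within [1.5, 2.5]
  expect_equal(poisson_dfsm_fraction(2, 25), dpois(2, 2), tolerance = 1e-12)
  expect_error(poisson_dfsm_fraction(0, 25), "lambda")

  # brute-force enumeration oracle over a (lambda, threshold) grid
  for (lam in c(0.5, 2, 4.4, 9, 20)) {
    for (th in c(0, 10, 25, 50, 100, 400)) {
      k <- 0:max(50, ceiling(lam * 6))
      oracle <- sum(dpois(k, lam)[abs(k - lam) / lam * 100 <= th])
      expect_equal(poisson_dfsm_fraction(lam, th), oracle, tolerance = 1e-9)
    }
  }
  # a wide enough band covers the whole support
  expect_equal(poisson_dfsm_fraction(5, 1e7), 1, tolerance = 1e-12)

  # Monte-Carlo route agrees with enumeration
  for (lam in c(1, 5, 20)) {
    mc <- poisson_dfsm_fraction_mc(lam, 25, n = 1e5, seed = 602)
    exact <- poisson_dfsm_fraction(lam, 25)
    expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 1e5) + 1e-6)
  }
})

test_that("variance-mean points use the n-1 sample variance", {
  p <- variance_mean_point(mk_counts(c(3, 3, 3)))
  expect_equal(p$mean, 3)
  expect_equal(p$variance, 0)
  p2 <- variance_mean_point(mk_counts(c(0, 2)))
  expect_equal(p2$mean, 1)
  expect_equal(p2$variance, 2)
  expect_error(variance_mean_point(mk_counts(5)), "at least 2")
})

test_that("overlap debias factor removes the finite-scan sliding bias", {
  # nonoverlapping windows need no correction
  expect_equal(overlap_debias_factor(35, 60, 60), 1)
  f <- overlap_debias_factor(1621, 480, 1)
  expect_lt(f, 0.8)
  expect_gt(f, 0.6)

  # empirical: debiased sliding variance is centred on the true variance
  # while the raw sliding variance is biased low by the factor 1 - rho_bar
  pts <- lapply(1:400, function(i) {
    s <- simulate_homogeneous_poisson(10, 2100, seed = child_seed(603, i))
    ic <- count_in_windows(s, interval_spec(480))
    list(raw = variance_mean_point(ic),
         deb = variance_mean_point(ic, debias_overlap = TRUE))
  })
  m <- mean(vapply(pts, function(p) p$raw$mean, numeric(1)))
  v_raw <- mean(vapply(pts, function(p) p$raw$variance, numeric(1)))
  v_deb <- mean(vapply(pts, function(p) p$deb$variance, numeric(1)))
  expect_equal(v_deb / m, 1, tolerance = 0.1)   # ~3 SE at 400 streams
  expect_lt(v_raw / m, 0.82)                    # true bias factor is ~0.73
})

test_that("zero-intercept fit recovers exact and degenerate slopes", {
  pts <- data.frame(mean = c(1, 2, 5), variance = 2 * c(1, 2, 5))
  expect_equal(zero_intercept_fit(pts), 2)
  expect_equal(zero_intercept_fit(data.frame(mean = 4, variance = 6)), 1.5)
  expect_error(zero_intercept_fit(data.frame(mean = 0, variance = 1)),
               "zero")
})

test_that("max/min ratios flag zero minima and honour the floor", {
  expect_equal(maxmin_rate_ratio(c(2, 4)), 2)
  expect_equal(maxmin_rate_ratio(c(3, 3, 3)), 1)
  expect_identical(maxmin_rate_ratio(c(0, 4)), Inf)
  expect_equal(maxmin_rate_ratio(c(0, 4), floor = 0.5), 8)
  expect_error(maxmin_rate_ratio(5), "at least 2")
  expect_error(maxmin_rate_ratio(c(-1, 2)), "non-negative")
})

test_that("split-scan ratio compares first and last 15-min segments", {
  # deterministic check: 10 events in the first segment, 5 in the last
  t1 <- seq(10, 890, length.out = 10)
  t2 <- seq(1210, 2090, length.out = 5)
  s <- event_series(c(t1, t2), 2100)
  expect_equal(split_scan_ratio(s), 2)
  expect_identical(split_scan_ratio(event_series(t1, 2100)), Inf)
  expect_error(split_scan_ratio(event_series(10, 1800)), "shorter")

  # rate doubling at mid-scan gives a ratio near 2 on average
  ratios <- vapply(1:150, function(i) {
    split_scan_ratio(simulate_changepoint_poisson(8, 16, 1050, 2100,
                                                  seed = child_seed(604, i)))
  }, numeric(1))
  expect_equal(median(ratios), 2, tolerance = 0.15)
  # homogeneous scans sit near 1
  ratios0 <- vapply(1:150, function(i) {
    split_scan_ratio(simulate_homogeneous_poisson(8, 2100,
                                                  seed = child_seed(605, i)))
  }, numeric(1))
  expect_lt(median(ratios0), 1.3)
})

test_that("KS statistic matches the brute-force ECDF sweep", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(0, 1)$statistic, 1)
  expect_error(ks_two_sample(numeric(), 1), "non-empty")

  set.seed(606)
  for (i in 1:100) {
    a <- round(rnorm(sample(2:30, 1)), 1)
    b <- round(rnorm(sample(2:30, 1), mean = runif(1, -1, 1)), 1)
    expect_equal(ks_two_sample(a, b)$statistic, brute_ks_D(a, b),
                 tolerance = 1e-12)
  }
})
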