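test_that("all generators are bit-reproducible under a fixed seed", {
  gens <- list(
    function(sd) simulate_homogeneous_poisson(5, 2100, seed = sd),
    function(sd) simulate_changepoint_poisson(4, 8, 1050, 2100, seed = sd),
    function(sd) simulate_merged_poisson(3, 6, 2100, seed = sd),
    function(sd) simulate_switching_shedding(1, 10, 5, 5, 2100, seed = sd),
    function(sd) simulate_diurnal_session(5, seed = sd)
  )
  for (g in gens) {
    a <- g(123)
    b <- g(123)
    c <- g(124)
    expect_identical(a, b)
    expect_false(identical(a, c))
  }
  # seeding must not clobber the caller's RNG stream
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(simulate_homogeneous_poisson(5, 600, seed = 9))
  expect_identical(runif(1), before)
})

test_that("zero rates give empty streams and negative inputs error", {
  expect_equal(n_events(simulate_homogeneous_poisson(0, 2100, seed = 1)), 0)
  expect_error(simulate_homogeneous_poisson(-1, 2100), "non-negative")
  expect_error(simulate_changepoint_poisson(4, 8, 0, 2100), "change_time")
  expect_error(simulate_changepoint_poisson(4, 8, 2100, 2100), "change_time")
  expect_error(simulate_merged_poisson(-1, 2, 600), "non-negative")
  expect_error(simulate_switching_shedding(1, 2, 0, 5, 600), "positive")
})

test_that("homogeneous generator hits the Poisson mean rate", {
  n_rep <- 2000
  counts <- vapply(seq_len(n_rep), function(i) {
    n_events(simulate_homogeneous_poisson(5, 2100, seed = child_seed(301, i)))
  }, numeric(1))
  se <- sqrt(175 / n_rep)
  expect_lt(abs(mean(counts) - 175), 3 * se)
  # and event times are uniform over the scan (KS against U(0, T))
  s <- simulate_homogeneous_poisson(10, 7200, seed = 302)
  ks <- suppressWarnings(stats::ks.test(s$times / 7200, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("change-point halves are homogeneous at their own rates", {
  n_rep <- 400
  first <- second <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- simulate_changepoint_poisson(4, 8, 1050, 2100,
                                      seed = child_seed(401, i))
    first[i] <- sum(s$times < 1050)
    second[i] <- sum(s$times >= 1050)
  }
  expect_lt(abs(mean(first) - 70), 3 * sqrt(70 / n_rep))
  expect_lt(abs(mean(second) - 140), 3 * sqrt(140 / n_rep))
})

test_that("pooled change-point counts match the 50/50 Poisson-mixture variance", {
  # 1-min non-overlapping windows, rate doubling at mid-scan: the pooled
  # counts are an equal mixture of Poisson(4) and Poisson(8)
  mu1 <- 4; mu2 <- 8
  vm_expected <- brute_mixture_variance(mu1, mu2)
  expect_equal(vm_expected, (mu1 + mu2) / 2 + (mu2 - mu1)^2 / 4,
               tolerance = 1e-9)  # closed form vs pmf mixing
  pooled <- unlist(lapply(seq_len(300), function(i) {
    s <- simulate_changepoint_poisson(mu1, mu2, 1050, 2100,
                                      seed = child_seed(402, i))
    count_in_windows(s, interval_spec(60, mode = "nonoverlapping"))$counts
  }))
  vmr_expected <- vm_expected / ((mu1 + mu2) / 2)   # 5/3 for 4 and 8
  expect_equal(var(pooled) / mean(pooled), vmr_expected, tolerance = 0.08)
})

test_that("merged streams are indistinguishable from summed-rate homogeneous", {
  # superposition property, checked suite-by-suite with a two-sample KS test
  pvals <- vapply(seq_len(40), function(i) {
    m <- simulate_merged_poisson(4, 8, 2100, seed = child_seed(403, i))
    h <- simulate_homogeneous_poisson(12, 2100, seed = child_seed(404, i))
    cm <- count_in_windows(m, interval_spec(60, mode = "nonoverlapping"))
    ch <- count_in_windows(h, interval_spec(60, mode = "nonoverlapping"))
    ks_two_sample(cm$counts, ch$counts)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
  # degenerate component: merged(0, r) is homogeneous(r)
  m0 <- simulate_merged_poisson(0, 6, 2100, seed = 405)
  h0 <- simulate_homogeneous_poisson(6, 2100, seed = 405)
  expect_identical(m0$times, h0$times)
})

test_that("switching generator has the renewal-reward long-run rate and is overdispersed", {
  r_lo <- 2; r_hi <- 20; d_lo <- 5; d_hi <- 10
  expected <- (r_lo * d_lo + r_hi * d_hi) / (d_lo + d_hi)
  n_rep <- 150
  dur <- 14400
  counts <- vapply(seq_len(n_rep), function(i) {
    n_events(simulate_switching_shedding(r_lo, r_hi, d_lo, d_hi, dur,
                                         seed = child_seed(406, i)))
  }, numeric(1))
  rate_hat <- mean(counts) / dur * 60
  # dwell randomness inflates the count variance well beyond Poisson;
  # bound the error with the empirical SE instead of the Poisson SE
  se_rate <- sd(counts) / sqrt(n_rep) / dur * 60
  expect_lt(abs(rate_hat - expected), 3 * se_rate)

  s <- simulate_switching_shedding(r_lo, r_hi, d_lo, d_hi, 28800, seed = 407)
  cc <- count_in_windows(s, interval_spec(60, mode = "nonoverlapping"))
  expect_gt(var(cc$counts) / mean(cc$counts), 1.5)

  # equal rates collapse to a homogeneous process
  eqr <- simulate_switching_shedding(5, 5, 5, 5, 2100, seed = 408)
  cc2 <- count_in_windows(eqr, interval_spec(60, mode = "nonoverlapping"))
  expect_lt(var(cc2$counts) / mean(cc2$counts), 2)
})

test_that("diurnal sessions scale scan rates by the multipliers", {
  sess <- simulate_diurnal_session(20, multipliers = c(0.2, 1, 2, 5),
                                   seed = 409)
  expect_equal(length(sess$scans), 4)
  r <- scan_rates(sess)
  # expected rates 4, 20, 40, 100 events/min over 50-min scans
  expect_equal(r, 20 * c(0.2, 1, 2, 5), tolerance = 0.2)
  expect_gt(maxmin_rate_ratio(r), 15)
  expect_lt(maxmin_rate_ratio(r), 40)

  flat <- simulate_diurnal_session(20, multipliers = rep(1, 4), seed = 410)
  expect_lt(maxmin_rate_ratio(scan_rates(flat)), 1.5)
  expect_error(simulate_diurnal_session(5, multipliers = c(0, 1, 1, 1),
                                        seed = 1), "positive")
})

test_that("log-uniform sessions are far more variable than flat ones", {
  ratio_med <- function(mult) {
    rr <- vapply(seq_len(40), function(i) {
      sess <- simulate_diurnal_session(
        10, multipliers = mult, seed = child_seed(411, i))
      maxmin_rate_ratio(scan_rates(sess))
    }, numeric(1))
    median(rr)
  }
  expect_gt(ratio_med(NULL) / ratio_med(rep(1, 4)), 5)
})

test_that("diurnal_session enforces its structural invariants", {
  mk <- function(n) event_series(numeric(), 3000)
  expect_error(diurnal_session(list(mk(), mk()), c(13, 7)), "increasing")
  expect_error(diurnal_session(list(mk(), mk()), c(0, 30)), "24")
  expect_error(
    diurnal_session(list(event_series(numeric(), 100),
                         event_series(numeric(), 200)), c(0, 6)),
    "equal duration")
})

test_that("the fixture suite is complete, deterministic and parseable", {
  dir1 <- file.path(withr::local_tempdir(), "a")
  dir2 <- file.path(withr::local_tempdir(), "b")
  m1 <- generate_fixture_suite(dir1, master_seed = 5, n_streams = 6,
                               n_sessions = 2)
  m2 <- generate_fixture_suite(dir2, master_seed = 5, n_streams = 6,
                               n_sessions = 2)
  expect_equal(length(m1$entries), 6 * 3 + 2)
  expect_identical(readLines(file.path(dir1, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))

  kinds <- vapply(m1$entries, function(e) e$kind, character(1))
  expect_equal(sum(kinds == "homogeneous"), 6)
  expect_equal(sum(kinds == "changepoint"), 6)
  expect_equal(sum(kinds == "merged"), 6)
  expect_equal(sum(kinds == "diurnal_session"), 2)

  for (e in m1$entries) {
    for (f in unlist(e$file)) {
      s <- read_event_series(file.path(dir1, f))
      expect_s3_class(validate_event_series(s), "event_series")
    }
    # manifest's realised counts match the files
    n <- sum(vapply(unlist(e$file), function(f) {
      n_events(read_event_series(file.path(dir1, f)))
    }, numeric(1)))
    expect_equal(n, e$n_events)
  }

  # replicate k is reproducible in isolation from its recorded child seed
  e <- m1$entries[[which(kinds == "changepoint")[3]]]
  s <- simulate_changepoint_poisson(e$rate1, e$rate2, e$change_time_s,
                                    e$duration_s, seed = e$seed)
  expect_equal(s$times, read_event_series(file.path(dir1, e$file))$times,
               tolerance = 1e-12)
})
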