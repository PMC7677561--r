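# Seeded generators for the event-stream models used throughout: homogeneous
# Poisson, change-point Poisson, merged (superposed) Poisson, two-state
# Markov-modulated Poisson, and diurnal multi-scan sessions. All kinds use one
# algorithm: exponential inter-arrival sampling at a piecewise-constant rate.

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule `(master * 48271 + index * 10007) mod
#' (2^31 - 1)` so that replicate `index` of a battery is reproducible in
#' isolation from the battery's master seed.
#'
#' @param master Master seed (integerish).
#' @param index Replicate index (integerish, may be vectorised).
#' @return Integer seed(s) in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 10007) %%
               2147483647)
}

# Homogeneous Poisson event times on [0, duration_s) at `rate` events/min,
# drawn from the *current* RNG stream via exponential inter-arrivals.
poisson_times <- function(rate, duration_s) {
  if (rate == 0) return(numeric())
  r_sec <- rate / 60
  times <- numeric(0)
  t_last <- 0
  repeat {
    k <- max(16L, ceiling(1.5 * r_sec * (duration_s - t_last)))
    tt <- t_last + cumsum(stats::rexp(k, rate = r_sec))
    times <- c(times, tt[tt < duration_s])
    if (tt[k] >= duration_s) break
    t_last <- tt[k]
  }
  times
}

#' Simulate a homogeneous Poisson event stream
#'
#' Event times are a realisation of a homogeneous Poisson process, generated
#' by exponential inter-arrival sampling; the expected event count is
#' `rate * duration / 60`.
#'
#' @param rate Mean detection rate in events per minute, non-negative.
#' @param duration Scan duration in seconds.
#' @param seed Integer seed for reproducibility, or `NULL` to draw from the
#'   current RNG stream.
#' @param label Series label.
#' @return An [event_series()].
#' @examples
#' s <- simulate_homogeneous_poisson(5, 2100, seed = 1)
#' event_rate(s)
#' @export
simulate_homogeneous_poisson <- function(rate, duration, seed = NULL,
                                         label = "homogeneous") {
  if (rate < 0) stop("`rate` must be non-negative (events/min)")
  times <- with_seed(seed, poisson_times(rate, duration))
  event_series(times, duration, label)
}

#' Simulate a change-point Poisson event stream
#'
#' Piecewise-homogeneous Poisson process: rate `rate1` on
#' `[0, change_time)` and `rate2` on `[change_time, duration)`. The standard
#' battery uses `rate2 = 2 * rate1` with the change at mid-scan.
#'
#' @param rate1,rate2 Segment rates in events per minute, non-negative.
#' @param change_time Change point in seconds, strictly inside
#'   `(0, duration)`.
#' @param duration Scan duration in seconds.
#' @param seed Integer seed or `NULL`.
#' @param label Series label.
#' @return An [event_series()].
#' @export
simulate_changepoint_poisson <- function(rate1, rate2, change_time, duration,
                                         seed = NULL, label = "changepoint") {
  if (rate1 < 0 || rate2 < 0) stop("rates must be non-negative (events/min)")
  if (change_time <= 0 || change_time >= duration) {
    stop("`change_time` must lie strictly inside (0, duration)")
  }
  times <- with_seed(seed, {
    c(poisson_times(rate1, change_time),
      change_time + poisson_times(rate2, duration - change_time))
  })
  event_series(times, duration, label)
}

#' Simulate the superposition of two Poisson event streams
#'
#' Union of two independent homogeneous realisations; by the superposition
#' property this is distributionally a single homogeneous process at
#' `rate1 + rate2`.
#'
#' @param rate1,rate2 Component rates in events per minute, non-negative.
#' @param duration Scan duration in seconds.
#' @param seed Integer seed or `NULL`.
#' @param label Series label.
#' @return An [event_series()].
#' @export
simulate_merged_poisson <- function(rate1, rate2, duration, seed = NULL,
                                    label = "merged") {
  if (rate1 < 0 || rate2 < 0) stop("rates must be non-negative (events/min)")
  times <- with_seed(seed, {
    sort(c(poisson_times(rate1, duration), poisson_times(rate2, duration)))
  })
  event_series(times, duration, label)
}

#' Simulate a two-state switching (Markov-modulated) Poisson stream
#'
#' Kinetic model oscillating between low- and high-shedding states:
#' exponentially distributed dwell times alternate the instantaneous Poisson
#' rate. The initial state is drawn from the stationary distribution, so the
#' long-run mean rate is the dwell-weighted average
#' `(rate_low * d_low + rate_high * d_high) / (d_low + d_high)`.
#'
#' @param rate_low,rate_high State rates in events per minute, non-negative.
#' @param mean_dwell_low,mean_dwell_high Mean dwell times in minutes, positive.
#' @param duration Scan duration in seconds.
#' @param seed Integer seed or `NULL`.
#' @param label Series label.
#' @return An [event_series()].
#' @export
simulate_switching_shedding <- function(rate_low, rate_high,
                                        mean_dwell_low, mean_dwell_high,
                                        duration, seed = NULL,
                                        label = "switching") {
  if (rate_low < 0 || rate_high < 0) stop("rates must be non-negative")
  if (mean_dwell_low <= 0 || mean_dwell_high <= 0) {
    stop("mean dwell times must be positive (minutes)")
  }
  times <- with_seed(seed, {
    low <- stats::runif(1) < mean_dwell_low / (mean_dwell_low + mean_dwell_high)
    t <- 0
    out <- numeric(0)
    while (t < duration) {
      dwell_s <- stats::rexp(1, rate = 1 / (60 * if (low) mean_dwell_low else
                                              mean_dwell_high))
      seg_end <- min(t + dwell_s, duration)
      rate <- if (low) rate_low else rate_high
      out <- c(out, t + poisson_times(rate, seg_end - t))
      t <- seg_end
      low <- !low
    }
    out
  })
  event_series(times, duration, label)
}

#' Diurnal session: an ordered set of scans spanning up to 24 h
#'
#' Bundles repeated scans of equal duration with their clock start times,
#' emulating four 50-min scans spread over a 24-h period.
#'
#' @param scans List of [event_series()] of equal duration.
#' @param start_hours Numeric vector of scan start times in hours, strictly
#'   increasing, measured from an arbitrary clock origin (values may exceed 24
#'   to place a scan on the following day); the span must be at most 24 h.
#' @param session_id Free-text identifier.
#' @return An object of class `diurnal_session`.
#' @export
diurnal_session <- function(scans, start_hours, session_id = "") {
  if (length(scans) != length(start_hours) || length(scans) < 1L) {
    stop("`scans` and `start_hours` must have equal positive length")
  }
  scans <- lapply(scans, validate_event_series)
  if (is.unsorted(start_hours, strictly = TRUE)) {
    stop("`start_hours` must be strictly increasing")
  }
  if (diff(range(start_hours)) > 24) {
    stop("scan start times must span at most 24 h")
  }
  durs <- vapply(scans, function(s) s$duration, numeric(1))
  if (length(unique(durs)) != 1L) {
    stop("all scans in a session must have equal duration")
  }
  structure(list(scans = scans, start_hours = as.numeric(start_hours),
                 session_id = as.character(session_id)[1]),
            class = "diurnal_session")
}

#' @export
print.diurnal_session <- function(x, ...) {
  cat(sprintf("<diurnal_session> '%s': %d scans of %.0f s at clock hours %s\n",
              x$session_id, length(x$scans), x$scans[[1]]$duration,
              paste(sprintf("%.0f", x$start_hours %% 24), collapse = ", ")))
  invisible(x)
}

#' Per-scan detection rates of a session
#' @param session A [diurnal_session()].
#' @return Numeric vector of rates in events per minute, one per scan.
#' @export
scan_rates <- function(session) {
  vapply(session$scans, event_rate, numeric(1))
}

#' Pooled 24-h mean detection rate of a session
#'
#' Total event count over all scans divided by total scanned time.
#'
#' @param session A [diurnal_session()].
#' @return Rate in events per minute.
#' @export
session_mean_rate <- function(session) {
  total <- sum(vapply(session$scans, n_events, numeric(1)))
  total / sum(vapply(session$scans, function(s) s$duration, numeric(1))) * 60
}

#' Simulate a diurnal session of repeated scans
#'
#' Each scan is a homogeneous Poisson stream at `base_rate * multiplier`, so
#' the expected session max/min rate ratio equals the max/min of the
#' multipliers. When `multipliers` is `NULL` they are drawn log-uniformly from
#' `multiplier_range`, whose default spans enough dynamic range for realised
#' session ratios of order 2-150.
#'
#' @param base_rate Baseline detection rate in events per minute.
#' @param multipliers Positive per-scan rate multipliers, or `NULL` to draw
#'   them log-uniformly from `multiplier_range`.
#' @param scan_duration Scan duration in seconds (default 3000 s = 50 min).
#' @param start_hours Scan start times in hours (default four scans 6 h apart
#'   starting at 7am).
#' @param seed Integer seed or `NULL`.
#' @param multiplier_range Two positive numbers; log-uniform sampling bounds.
#' @param session_id Session identifier.
#' @return A [diurnal_session()].
#' @export
simulate_diurnal_session <- function(base_rate, multipliers = NULL,
                                     scan_duration = 3000,
                                     start_hours = c(7, 13, 19, 25),
                                     seed = NULL,
                                     multiplier_range = c(1, 150),
                                     session_id = "session") {
  if (base_rate < 0) stop("`base_rate` must be non-negative (events/min)")
  n_scan <- length(start_hours)
  with_seed(seed, {
    if (is.null(multipliers)) {
      multipliers <- exp(stats::runif(n_scan, log(multiplier_range[1]),
                                      log(multiplier_range[2])))
    }
    if (length(multipliers) != n_scan) {
      stop("`multipliers` must match the number of scan start times")
    }
    if (any(multipliers <= 0)) stop("multipliers must be strictly positive")
    scans <- lapply(seq_len(n_scan), function(i) {
      event_series(poisson_times(base_rate * multipliers[i], scan_duration),
                   scan_duration,
                   label = sprintf("%s-scan%d", session_id, i))
    })
    diurnal_session(scans, start_hours, session_id)
  })
}

#' Generate the standard in-silico fixture battery
#'
#' Writes a deterministic in-silico battery: `n_streams`
#' homogeneous 35-min streams with rates log-spaced across `rate_range`
#' (default 0.6-19.6 events/min, the detection-rate range of the abundant-CTC
#' cohort), the same number of change-point streams (`rate2 = 2 * rate1`,
#' change at mid-scan) and merged streams (components `rate1` and
#' `2 * rate1`), plus `n_sessions` diurnal sessions of four 50-min scans with
#' log-uniform multipliers, half starting at 7am and half at 7pm. Every stream
#' gets its own [child_seed()] so it is reproducible in isolation, and a JSON
#' manifest records the full simulation spec and realised event count of each
#' file.
#'
#' @param output_dir Directory to create/write into.
#' @param master_seed Master seed for the battery.
#' @param n_streams Streams per 35-min model kind (default 54).
#' @param n_sessions Number of diurnal sessions (default 14).
#' @param rate_range Two positive rates (events/min) bounding the log-spaced
#'   grid.
#' @param duration 35-min stream duration in seconds.
#' @param scan_duration Session scan duration in seconds.
#' @param multiplier_range Log-uniform bounds for session multipliers.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
generate_fixture_suite <- function(output_dir, master_seed = 1,
                                   n_streams = 54L, n_sessions = 14L,
                                   rate_range = c(0.6, 19.6),
                                   duration = 2100, scan_duration = 3000,
                                   multiplier_range = c(1, 150)) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output dir: ", output_dir)
  rates <- exp(seq(log(rate_range[1]), log(rate_range[2]),
                   length.out = n_streams))
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e

  for (i in seq_len(n_streams)) {
    r <- rates[i]

    sd1 <- child_seed(master_seed, i)
    lab <- sprintf("homogeneous_%02d", i)
    s <- simulate_homogeneous_poisson(r, duration, seed = sd1, label = lab)
    f <- file.path(output_dir, paste0(lab, ".csv"))
    write_event_series(s, f)
    add(list(file = basename(f), kind = "homogeneous", rate1 = r,
             duration_s = duration, seed = sd1, n_events = n_events(s)))

    sd2 <- child_seed(master_seed, 1000L + i)
    lab <- sprintf("changepoint_%02d", i)
    s <- simulate_changepoint_poisson(r, 2 * r, duration / 2, duration,
                                      seed = sd2, label = lab)
    f <- file.path(output_dir, paste0(lab, ".csv"))
    write_event_series(s, f)
    add(list(file = basename(f), kind = "changepoint", rate1 = r,
             rate2 = 2 * r, change_time_s = duration / 2,
             duration_s = duration, seed = sd2, n_events = n_events(s)))

    sd3 <- child_seed(master_seed, 2000L + i)
    lab <- sprintf("merged_%02d", i)
    s <- simulate_merged_poisson(r, 2 * r, duration, seed = sd3, label = lab)
    f <- file.path(output_dir, paste0(lab, ".csv"))
    write_event_series(s, f)
    add(list(file = basename(f), kind = "merged", rate1 = r, rate2 = 2 * r,
             duration_s = duration, seed = sd3, n_events = n_events(s)))
  }

  base_rates <- exp(seq(log(rate_range[1]), log(rate_range[2]),
                        length.out = n_sessions))
  for (j in seq_len(n_sessions)) {
    sdj <- child_seed(master_seed, 3000L + j)
    first <- if (j %% 2 == 1) 7 else 19   # alternate 7am / 7pm session starts
    sid <- sprintf("session_%02d", j)
    sess <- simulate_diurnal_session(
      base_rates[j], scan_duration = scan_duration,
      start_hours = first + c(0, 6, 12, 18), seed = sdj,
      multiplier_range = multiplier_range, session_id = sid
    )
    files <- character(length(sess$scans))
    for (k in seq_along(sess$scans)) {
      files[k] <- sprintf("%s_scan%d.csv", sid, k)
      write_event_series(sess$scans[[k]], file.path(output_dir, files[k]))
    }
    add(list(file = files, kind = "diurnal_session", session_id = sid,
             base_rate = base_rates[j], start_hours = first + c(0, 6, 12, 18),
             duration_s = scan_duration, seed = sdj,
             n_events = sum(vapply(sess$scans, n_events, numeric(1)))))
  }

  manifest <- list(master_seed = master_seed, n_streams = n_streams,
                   n_sessions = n_sessions, entries = entries)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a diurnal session back from a fixture directory
#'
#' @param dir Fixture directory containing the session scan files.
#' @param entry A `diurnal_session` manifest entry (list with `file`,
#'   `start_hours`, `session_id`).
#' @return A [diurnal_session()].
#' @export
read_diurnal_session <- function(dir, entry) {
  scans <- lapply(unlist(entry$file),
                  function(f) read_event_series(file.path(dir, f)))
  diurnal_session(scans, unlist(entry$start_hours), entry$session_id)
}
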