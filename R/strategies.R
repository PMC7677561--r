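# Blood-sampling strategy evaluation: how well do one large contiguous
# equivalent blood sample versus several temporally separated small samples
# estimate the 24-h mean CTC count?

#' Sampling strategy specification
#'
#' Describes a strategy of `n_samples` equivalent blood samples of
#' `sample_window` seconds each, drawn at least `min_separation` hours apart
#' within a diurnal session. The per-draw estimate is the mean count across
#' the samples, compared (as a DFSM) against the session's 24-h mean count
#' per window of the same length.
#'
#' @param n_samples Number of samples per draw, at least 1.
#' @param sample_window Length of each sample in seconds (24 s is about 1% of
#'   the mouse PBV at the default scan configuration).
#' @param min_separation Minimum separation between sample start times in
#'   hours (default 6).
#' @param label Display label; defaults to e.g. `"4 x 24 s"`.
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(n_samples, sample_window, min_separation = 6,
                          label = NULL) {
  if (n_samples < 1L) stop("`n_samples` must be at least 1")
  if (sample_window <= 0) stop("`sample_window` must be positive (seconds)")
  if (min_separation < 0) stop("`min_separation` must be non-negative (hours)")
  if (is.null(label)) {
    label <- sprintf("%d x %g s", n_samples, sample_window)
  }
  structure(list(n_samples = as.integer(n_samples),
                 sample_window = sample_window,
                 min_separation = min_separation, label = label),
            class = "strategy_spec")
}

# Candidate offsets (s) of a sample window within one scan.
offset_grid <- function(scan_duration, window, stride) {
  if (window > scan_duration) {
    stop("sample window longer than a scan: infeasible strategy")
  }
  n <- floor((scan_duration - window) / stride + 1e-9) + 1
  (seq_len(n) - 1) * stride
}

#' Enumerate the draws of a sampling strategy over a session
#'
#' A draw is a placement of the strategy's `n_samples` windows inside the
#' session's scans such that every pair of sample start times is at least
#' `min_separation` hours apart. Positions come from a per-scan offset grid
#' with step `stride`. Two modes:
#'
#' * `"exhaustive"`: every feasible placement on the grid (errors if more
#'   than `max_draws` would result; the 4-sample fine-grid case is
#'   combinatorially large, use `"random"` there).
#' * `"random"`: `n_draws` seeded draws; each picks `n_samples` distinct
#'   scans uniformly, one grid offset per scan, then assigns the sorted
#'   offsets to the scans in chronological order (with scans exactly
#'   `min_separation` apart this is what keeps consecutive start times
#'   separated); placements violating the constraint are rejected and
#'   redrawn.
#'
#' @param session A [diurnal_session()].
#' @param spec A [strategy_spec()].
#' @param stride Grid step in seconds (default: the sample window, i.e. a
#'   non-overlapping grid).
#' @param mode `"exhaustive"` or `"random"`.
#' @param n_draws Number of draws in random mode.
#' @param seed Integer seed for random mode.
#' @param max_draws Cap on exhaustive enumeration size.
#' @return A data frame with columns `draw`, `sample`, `scan`, `offset_s`,
#'   `abs_start_h` (one row per placed sample).
#' @export
enumerate_strategy_draws <- function(session, spec,
                                     stride = spec$sample_window,
                                     mode = c("exhaustive", "random"),
                                     n_draws = 200, seed = NULL,
                                     max_draws = 20000) {
  mode <- match.arg(mode)
  if (!inherits(session, "diurnal_session")) {
    stop("`session` must be a diurnal_session")
  }
  n_scan <- length(session$scans)
  dur <- session$scans[[1]]$duration
  offs <- offset_grid(dur, spec$sample_window, stride)
  sep_s <- spec$min_separation * 3600
  same_scan_ok <- sep_s <= dur - spec$sample_window
  if (spec$n_samples > 1L && !same_scan_ok && spec$n_samples > n_scan) {
    stop("infeasible strategy: separation forces distinct scans but ",
         "n_samples exceeds the number of scans")
  }

  abs_start <- function(scan, off) session$start_hours[scan] * 3600 + off

  if (spec$n_samples == 1L) {
    draws <- expand.grid(scan = seq_len(n_scan), offset_s = offs)
    if (mode == "random") {
      draws <- with_seed(seed, {
        idx <- sample.int(nrow(draws), n_draws, replace = TRUE)
        draws[idx, , drop = FALSE]
      })
    }
    out <- data.frame(draw = seq_len(nrow(draws)), sample = 1L,
                      scan = draws$scan, offset_s = draws$offset_s)
  } else if (mode == "exhaustive") {
    # depth-first over placements sorted by absolute time with pruning
    pos <- expand.grid(scan = seq_len(n_scan), offset_s = offs)
    pos$abs_s <- abs_start(pos$scan, pos$offset_s)
    pos <- pos[order(pos$abs_s), ]
    tuples <- list()
    recurse <- function(start_idx, chosen) {
      if (length(chosen) == spec$n_samples) {
        tuples[[length(tuples) + 1L]] <<- chosen
        if (length(tuples) > max_draws) {
          stop("exhaustive enumeration exceeds max_draws (", max_draws,
               "); use mode = \"random\"")
        }
        return()
      }
      for (i in seq(start_idx, nrow(pos))) {
        if (length(chosen) > 0 &&
            pos$abs_s[i] - pos$abs_s[chosen[length(chosen)]] < sep_s) next
        if (nrow(pos) - i + 1 < spec$n_samples - length(chosen)) break
        recurse(i + 1L, c(chosen, i))
      }
    }
    recurse(1L, integer())
    if (length(tuples) == 0L) {
      stop("infeasible strategy: no placement satisfies the separation")
    }
    out <- do.call(rbind, lapply(seq_along(tuples), function(d) {
      idx <- tuples[[d]]
      data.frame(draw = d, sample = seq_along(idx), scan = pos$scan[idx],
                 offset_s = pos$offset_s[idx])
    }))
  } else {
    out <- with_seed(seed, {
      rows <- vector("list", n_draws)
      for (d in seq_len(n_draws)) {
        ok <- FALSE
        for (attempt in seq_len(100L)) {
          scans <- sort(sample.int(n_scan, spec$n_samples))
          o <- sort(offs[sample.int(length(offs), spec$n_samples,
                                    replace = same_scan_ok)])
          starts <- abs_start(scans, o)
          if (all(diff(sort(starts)) >= sep_s - 1e-9)) { ok <- TRUE; break }
        }
        if (!ok) {
          stop("infeasible strategy: could not satisfy the separation ",
               "constraint after 100 attempts")
        }
        rows[[d]] <- data.frame(draw = d, sample = seq_len(spec$n_samples),
                                scan = scans, offset_s = o)
      }
      do.call(rbind, rows)
    })
  }
  out$abs_start_h <- abs_start(out$scan, out$offset_s) / 3600
  rownames(out) <- NULL
  out
}

# Count events of scan `scan` in [offset, offset + window).
sample_count <- function(session, scan, offset, window) {
  t <- session$scans[[scan]]$times
  findInterval(offset + window, t, left.open = TRUE) -
    findInterval(offset, t, left.open = TRUE)
}

#' Enumeration accuracy of a sampling strategy
#'
#' For every draw of the strategy, the estimate is the mean count across its
#' samples; its DFSM is computed against the session's 24-h reference, the
#' pooled mean count per window of the same length
#' (`session_mean_rate * window`). Returns the fraction of draws whose DFSM
#' is at or below `threshold`.
#'
#' @param session A [diurnal_session()] with a positive pooled mean rate.
#' @param spec A [strategy_spec()].
#' @param threshold DFSM threshold in percent (default 25).
#' @param mode,n_draws,seed,stride Passed to [enumerate_strategy_draws()];
#'   `mode` defaults to exhaustive for single-sample strategies and random
#'   otherwise.
#' @return Fraction of draws in `[0, 1]`.
#' @export
strategy_accuracy <- function(session, spec, threshold = 25,
                              mode = NULL, n_draws = 200, seed = NULL,
                              stride = spec$sample_window) {
  if (is.null(mode)) {
    mode <- if (spec$n_samples == 1L) "exhaustive" else "random"
  }
  ref <- session_mean_rate(session) / 60 * spec$sample_window
  if (ref <= 0) stop("session 24-h mean is zero: DFSM reference undefined")
  draws <- enumerate_strategy_draws(session, spec, stride = stride,
                                    mode = mode, n_draws = n_draws,
                                    seed = seed)
  counts <- mapply(sample_count, draws$scan, draws$offset_s,
                   MoreArgs = list(session = session,
                                   window = spec$sample_window))
  est <- tapply(counts, draws$draw, mean)
  mean(abs(est - ref) / ref * 100 <= threshold)
}

#' Paired comparison of two equal-volume sampling strategies
#'
#' Computes `strategy_accuracy(multi) - strategy_accuracy(single)` on the
#' same session for two strategies of equal total sampled volume
#' (`n_samples * sample_window` must match). A positive difference means the
#' temporally spread strategy estimated the 24-h mean more reliably than the
#' contiguous one.
#'
#' @param session A [diurnal_session()].
#' @param multi,single [strategy_spec()]s of equal total volume.
#' @param threshold DFSM threshold in percent (default 25).
#' @param n_draws,seed Passed to [strategy_accuracy()] (the single strategy
#'   uses `seed + 1` when a seed is given).
#' @return The paired accuracy difference in `[-1, 1]`.
#' @export
paired_strategy_comparison <- function(session, multi, single, threshold = 25,
                                       n_draws = 200, seed = NULL) {
  v_multi <- multi$n_samples * multi$sample_window
  v_single <- single$n_samples * single$sample_window
  if (abs(v_multi - v_single) > 1e-9) {
    stop("strategies must have equal total sampled volume")
  }
  a_multi <- strategy_accuracy(session, multi, threshold = threshold,
                               n_draws = n_draws, seed = seed)
  a_single <- strategy_accuracy(session, single, threshold = threshold,
                                n_draws = n_draws,
                                seed = if (is.null(seed)) NULL else seed + 1L)
  a_multi - a_single
}

#' The standard strategy grid
#'
#' The eight sample-size / sample-number combinations evaluated in the
#' strategy analysis, expressed as scan-time windows at the default scan
#' configuration (24 s of scan time is about 1% of the PBV): 1%, 2%, two 1%,
#' 4%, four 1%, 20%, 80% and four 20% samples.
#'
#' @param min_separation Minimum separation in hours for multi-sample
#'   strategies.
#' @return Named list of [strategy_spec()]s.
#' @export
standard_strategy_grid <- function(min_separation = 6) {
  list(
    `1%`       = strategy_spec(1, 24,   min_separation, label = "1%"),
    `2%`       = strategy_spec(1, 48,   min_separation, label = "2%"),
    `two 1%`   = strategy_spec(2, 24,   min_separation, label = "two 1%"),
    `4%`       = strategy_spec(1, 96,   min_separation, label = "4%"),
    `four 1%`  = strategy_spec(4, 24,   min_separation, label = "four 1%"),
    `20%`      = strategy_spec(1, 480,  min_separation, label = "20%"),
    `80%`      = strategy_spec(1, 1920, min_separation, label = "80%"),
    `four 20%` = strategy_spec(4, 480,  min_separation, label = "four 20%")
  )
}
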