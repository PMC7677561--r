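# Pipeline layer: a run configuration plus simulate -> analyze -> report
# stages operating on fixture directories. All result surfaces are CSV/JSON;
# figures are side artifacts.

SUMMARY_SCHEMA_VERSION <- "1.0"

#' Pipeline run configuration
#'
#' Bundles every knob of the simulate/analyze/report pipeline into one
#' serializable list; re-running a persisted configuration reproduces
#' identical CSV/JSON outputs.
#'
#' @param output_dir Directory for fixtures and results.
#' @param master_seed Master seed for all randomness.
#' @param n_streams Streams per 35-min model kind.
#' @param n_sessions Number of diurnal sessions.
#' @param windows Window lengths in seconds analysed per scan.
#' @param stride Sliding stride in seconds.
#' @param thresholds DFSM thresholds in percent.
#' @param rate_range Log-spaced rate grid bounds (events/min).
#' @param duration 35-min stream duration (s).
#' @param scan_duration Session scan duration (s).
#' @param multiplier_range Log-uniform session multiplier bounds.
#' @param strategy_draws Random draws per multi-sample strategy.
#' @param inclusion_rule Scan inclusion rule, see [inclusion_filter()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, master_seed = 1, n_streams = 54L,
                       n_sessions = 14L, windows = c(24, 120, 240, 480),
                       stride = 1, thresholds = c(25, 50),
                       rate_range = c(0.6, 19.6), duration = 2100,
                       scan_duration = 3000, multiplier_range = c(1, 150),
                       strategy_draws = 200L,
                       inclusion_rule = "any_detection") {
  structure(list(output_dir = output_dir, master_seed = master_seed,
                 n_streams = as.integer(n_streams),
                 n_sessions = as.integer(n_sessions), windows = windows,
                 stride = stride, thresholds = thresholds,
                 rate_range = rate_range, duration = duration,
                 scan_duration = scan_duration,
                 multiplier_range = multiplier_range,
                 strategy_draws = as.integer(strategy_draws),
                 inclusion_rule = inclusion_rule),
            class = "run_config")
}

#' Simulate stage: write the fixture battery of a run
#'
#' Delegates to [generate_fixture_suite()] with the configuration's
#' parameters; fixtures land in `<output_dir>/fixtures`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
pipeline_simulate <- function(config) {
  generate_fixture_suite(
    file.path(config$output_dir, "fixtures"),
    master_seed = config$master_seed, n_streams = config$n_streams,
    n_sessions = config$n_sessions, rate_range = config$rate_range,
    duration = config$duration, scan_duration = config$scan_duration,
    multiplier_range = config$multiplier_range
  )
}

#' Analyze stage: per-scan tables, cohort fits, session and strategy summaries
#'
#' Reads the fixture battery, applies the inclusion rule, and computes per
#' scan and window size: window counts (sliding, configurable stride), mean,
#' plain and overlap-debiased variance, detection fraction, DFSM threshold
#' fractions and their Poisson references. Per model kind and window size it
#' fits the zero-intercept variance-mean slope (on the debiased variances).
#' For diurnal sessions it computes per-scan rates and max/min ratios, a KS
#' comparison of the 24-h ratios against the within-scan split ratios of the
#' homogeneous streams, and the standard sampling-strategy grid with paired
#' equal-volume comparisons. Writes `scans.csv`, `slopes.csv`, `sessions.csv`,
#' `strategies.csv`, `paired.csv` and `summary.json` under
#' `<output_dir>/results`.
#'
#' @param config A [run_config()].
#' @param fixtures_dir Fixture directory (default `<output_dir>/fixtures`).
#' @param figures If `TRUE`, also render diagnostic figures to
#'   `results/figures.pdf`.
#' @return Invisibly, the summary list (the content of `summary.json`).
#' @export
pipeline_analyze <- function(config,
                             fixtures_dir = file.path(config$output_dir,
                                                      "fixtures"),
                             figures = FALSE) {
  manifest_path <- file.path(fixtures_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", fixtures_dir)
  manifest <- jsonlite::read_json(manifest_path)
  res_dir <- file.path(config$output_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

  stream_entries <- Filter(function(e) e$kind != "diurnal_session",
                           manifest$entries)
  session_entries <- Filter(function(e) e$kind == "diurnal_session",
                            manifest$entries)

  scan_rows <- list()
  excluded <- character()
  series_by_file <- list()
  for (e in stream_entries) {
    s <- tryCatch(read_event_series(file.path(fixtures_dir, e$file)),
                  error = function(err) {
                    warning("skipping unreadable file ", e$file, ": ",
                            conditionMessage(err))
                    NULL
                  })
    if (is.null(s)) next
    if (!inclusion_filter(s, config$inclusion_rule)) {
      excluded <- c(excluded, e$file)
      next
    }
    series_by_file[[e$file]] <- list(series = s, kind = e$kind)
    for (w in config$windows) {
      ic <- count_in_windows(s, interval_spec(w, stride = config$stride))
      vm <- variance_mean_point(ic, debias_overlap = TRUE)
      lam <- scan_mean(ic)
      row <- data.frame(file = e$file, kind = e$kind, window = w,
                        n_windows = length(ic$counts), mean = lam,
                        variance = stats::var(ic$counts),
                        variance_debiased = vm$variance,
                        detection_fraction = detection_fraction(ic),
                        stringsAsFactors = FALSE)
      for (th in config$thresholds) {
        col <- paste0("dfsm", th)
        row[[col]] <- if (lam > 0) {
          dfsm_threshold_fraction(dfsm(ic, thresholds = config$thresholds), th)
        } else NA_real_
        row[[paste0("poisson_", col)]] <- if (lam > 0) {
          poisson_dfsm_fraction(lam, th)
        } else NA_real_
      }
      scan_rows[[length(scan_rows) + 1L]] <- row
    }
  }
  scans <- do.call(rbind, scan_rows)
  if (is.null(scans)) {
    scans <- data.frame(file = character(), kind = character(),
                        window = numeric(), n_windows = integer(),
                        mean = numeric(), variance = numeric(),
                        variance_debiased = numeric(),
                        detection_fraction = numeric())
  }

  slope_rows <- list()
  for (kind in unique(scans$kind)) {
    for (w in config$windows) {
      pts <- scans[scans$kind == kind & scans$window == w, ]
      pts <- data.frame(mean = pts$mean, variance = pts$variance_debiased)
      slope_rows[[length(slope_rows) + 1L]] <- data.frame(
        kind = kind, window = w, n_scans = nrow(pts),
        slope = zero_intercept_fit(pts), stringsAsFactors = FALSE)
    }
  }
  slopes <- do.call(rbind, slope_rows)
  if (is.null(slopes)) {
    slopes <- data.frame(kind = character(), window = numeric(),
                         n_scans = integer(), slope = numeric())
  }

  session_rows <- list()
  strategy_rows <- list()
  paired_rows <- list()
  grid <- standard_strategy_grid()
  paired_cases <- list(c("two 1%", "2%"), c("four 1%", "4%"),
                       c("four 20%", "80%"))
  for (e in session_entries) {
    sess <- read_diurnal_session(fixtures_dir, e)
    rates <- scan_rates(sess)
    session_rows[[length(session_rows) + 1L]] <- data.frame(
      session_id = e$session_id, n_scans = length(rates),
      mean_rate = session_mean_rate(sess),
      maxmin_ratio = maxmin_rate_ratio(rates), stringsAsFactors = FALSE)
    if (session_mean_rate(sess) <= 0) next
    seed0 <- child_seed(config$master_seed, 5000L + length(session_rows))
    for (gi in seq_along(grid)) {
      acc <- strategy_accuracy(sess, grid[[gi]],
                               threshold = config$thresholds[1],
                               n_draws = config$strategy_draws,
                               seed = child_seed(seed0, gi))
      strategy_rows[[length(strategy_rows) + 1L]] <- data.frame(
        session_id = e$session_id, strategy = grid[[gi]]$label,
        threshold = config$thresholds[1], accuracy = acc,
        stringsAsFactors = FALSE)
    }
    for (pc in paired_cases) {
      d <- paired_strategy_comparison(sess, grid[[pc[1]]], grid[[pc[2]]],
                                      threshold = config$thresholds[1],
                                      n_draws = config$strategy_draws,
                                      seed = child_seed(seed0, 100L))
      paired_rows[[length(paired_rows) + 1L]] <- data.frame(
        session_id = e$session_id, multi = pc[1], single = pc[2],
        difference = d, stringsAsFactors = FALSE)
    }
  }
  sessions <- do.call(rbind, session_rows)
  strategies <- do.call(rbind, strategy_rows)
  paired <- do.call(rbind, paired_rows)

  # 24-h between-scan ratios vs within-scan split ratios of homogeneous streams
  ks <- NULL
  if (!is.null(sessions) && nrow(sessions) >= 1) {
    homog <- Filter(function(x) x$kind == "homogeneous", series_by_file)
    split_ratios <- vapply(homog, function(x) split_scan_ratio(x$series),
                           numeric(1))
    sr <- sessions$maxmin_ratio
    a <- sr[is.finite(sr)]
    b <- split_ratios[is.finite(split_ratios)]
    if (length(a) >= 1 && length(b) >= 1) {
      kt <- ks_two_sample(a, b)
      ks <- list(comparison = "session_maxmin_vs_homogeneous_split",
                 n_a = length(a), n_b = length(b),
                 D = kt$statistic, p_value = kt$p.value)
    }
  }

  utils::write.csv(scans, file.path(res_dir, "scans.csv"), row.names = FALSE)
  utils::write.csv(slopes, file.path(res_dir, "slopes.csv"),
                   row.names = FALSE)
  if (!is.null(sessions)) {
    utils::write.csv(sessions, file.path(res_dir, "sessions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(strategies)) {
    utils::write.csv(strategies, file.path(res_dir, "strategies.csv"),
                     row.names = FALSE)
  }
  if (!is.null(paired)) {
    utils::write.csv(paired, file.path(res_dir, "paired.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    schema_version = SUMMARY_SCHEMA_VERSION,
    master_seed = config$master_seed,
    windows = config$windows,
    thresholds = config$thresholds,
    n_scans_included = length(series_by_file),
    n_scans_excluded = length(excluded),
    excluded_files = excluded,
    slopes = slopes,
    detection_fraction_median = if (nrow(scans) == 0) list() else
      stats::aggregate(detection_fraction ~ kind + window, data = scans,
                       FUN = stats::median),
    sessions = if (is.null(sessions)) list() else sessions,
    ks = ks,
    strategy_accuracy_median = if (is.null(strategies)) list() else
      stats::aggregate(accuracy ~ strategy, data = strategies,
                       FUN = stats::median),
    paired_positive_fraction = if (is.null(paired)) list() else
      stats::aggregate(difference ~ multi + single, data = paired,
                       FUN = function(d) mean(d > 0))
  )
  jsonlite::write_json(summary, file.path(res_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  if (figures) {
    pipeline_figures(config, scans, series_by_file,
                     file.path(res_dir, "figures.pdf"))
  }
  invisible(summary)
}

pipeline_figures <- function(config, scans, series_by_file, path) {
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  if (length(series_by_file) > 0) {
    print(plot_raster(series_by_file[[length(series_by_file)]]$series))
  }
  for (w in config$windows) {
    pts <- scans[scans$window == w, ]
    pts <- data.frame(mean = pts$mean, variance = pts$variance_debiased,
                      kind = pts$kind)
    print(plot_variance_mean(pts, title = sprintf("%g s windows", w)))
  }
  invisible(path)
}

#' Report stage: render a plain-text summary of an analysis
#'
#' Formats the `summary.json` of [pipeline_analyze()] into a fixed-layout
#' text report (inclusion counts, median detection fractions, variance-mean
#' slopes, session ratios with the KS comparison, and the strategy grid).
#' Rendering is deterministic: regenerating from the same summary yields
#' byte-identical text.
#'
#' @param summary A summary list or the path to a `summary.json`.
#' @param out_path Optional file to write the report to.
#' @return The report as a character vector of lines, invisibly when
#'   `out_path` is given.
#' @export
pipeline_report <- function(summary, out_path = NULL) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  req <- c("schema_version", "n_scans_included", "slopes",
           "detection_fraction_median")
  miss <- setdiff(req, names(summary))
  if (length(miss) > 0) {
    stop("summary does not match the report schema; missing: ",
         paste(miss, collapse = ", "))
  }
  as_df <- function(x) {
    if (is.data.frame(x)) x else do.call(rbind, lapply(x, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  lines <- c(
    "== CTC detection-stream analysis report ==",
    sprintf("schema %s | master seed %s", summary$schema_version,
            summary$master_seed),
    sprintf("scans included: %d; excluded by inclusion rule: %d",
            summary$n_scans_included, summary$n_scans_excluded)
  )
  if (summary$n_scans_included == 0) {
    lines <- c(lines, "no scans passed inclusion")
  }
  df <- as_df(summary$detection_fraction_median)
  if (!is.null(df) && nrow(df) > 0) {
    lines <- c(lines, "", "-- Median fraction of windows with >= 1 detection --")
    for (i in seq_len(nrow(df))) {
      lines <- c(lines, sprintf("  %-12s %6g s: %.3f", df$kind[i],
                                df$window[i], df$detection_fraction[i]))
    }
  }
  sl <- as_df(summary$slopes)
  if (!is.null(sl) && nrow(sl) > 0) {
    lines <- c(lines, "", "-- Zero-intercept variance-mean slopes --")
    for (i in seq_len(nrow(sl))) {
      lines <- c(lines, sprintf("  %-12s %6g s: slope %.3f (n = %d)",
                                sl$kind[i], sl$window[i], sl$slope[i],
                                sl$n_scans[i]))
    }
  }
  se <- as_df(summary$sessions)
  if (!is.null(se) && length(se) > 0 && nrow(se) > 0) {
    lines <- c(lines, "", "-- Diurnal sessions: max/min scan-rate ratios --",
               sprintf("  n = %d, median ratio %.2f, range %.2f-%.2f",
                       nrow(se), stats::median(se$maxmin_ratio),
                       min(se$maxmin_ratio), max(se$maxmin_ratio)))
    if (!is.null(summary$ks)) {
      lines <- c(lines, sprintf(
        "  KS vs within-scan split ratios: D = %.3f, p = %.3g",
        summary$ks$D, summary$ks$p_value))
    }
  }
  sa <- as_df(summary$strategy_accuracy_median)
  if (!is.null(sa) && length(sa) > 0 && nrow(sa) > 0) {
    lines <- c(lines, "", "-- Median strategy accuracy (DFSM <= threshold) --")
    for (i in seq_len(nrow(sa))) {
      lines <- c(lines, sprintf("  %-10s: %.3f", sa$strategy[i],
                                sa$accuracy[i]))
    }
  }
  pp <- as_df(summary$paired_positive_fraction)
  if (!is.null(pp) && length(pp) > 0 && nrow(pp) > 0) {
    lines <- c(lines, "", "-- Spread-vs-contiguous paired wins --")
    for (i in seq_len(nrow(pp))) {
      lines <- c(lines, sprintf("  %s beats %s in %.0f%% of sessions",
                                pp$multi[i], pp$single[i],
                                100 * pp$difference[i]))
    }
  }
  if (!is.null(out_path)) {
    writeLines(lines, out_path)
    return(invisible(lines))
  }
  lines
}
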