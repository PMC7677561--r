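# Core domain types: event series, scan configuration, interval specification,
# and the interval <-> volume <-> blood-fraction conversion layer.

#' Detection event series
#'
#' An `event_series` holds one scan's sorted detection timestamps (seconds from
#' scan start) together with the scan duration. It is the atomic input of every
#' analysis in the package. The central modelling assumption is that the event
#' count in a time interval equals the count that a drawn blood sample of the
#' corresponding volume would contain (see [interval_to_volume()]).
#'
#' @param times Numeric vector of event times in seconds, each in
#'   `[0, duration)`. Unsorted input is sorted. Exact duplicates are allowed
#'   (two cells can be detected within one clock tick) but trigger a warning.
#' @param duration Scan duration in seconds, strictly positive.
#' @param label Free-text identifier for the scan.
#' @return An object of class `event_series` with elements `times`, `duration`
#'   and `label`.
#' @examples
#' s <- event_series(c(12, 40.5, 301), duration = 2100, label = "scan-1")
#' n_events(s)
#' @seealso [validate_event_series()], [count_in_windows()]
#' @export
event_series <- function(times = numeric(), duration, label = "") {
  x <- structure(
    list(times = as.numeric(times), duration = as.numeric(duration),
         label = as.character(label)[1]),
    class = "event_series"
  )
  validate_event_series(x)
}

#' Validate an event series
#'
#' Checks the `event_series` invariants: positive duration, finite times, all
#' times within `[0, duration)`. Times are sorted if needed; exact duplicate
#' timestamps are kept but reported with a warning.
#'
#' @param series An `event_series` (or a bare list with the same fields).
#' @return The validated (sorted) `event_series`.
#' @export
validate_event_series <- function(series) {
  if (!is.list(series) || is.null(series$times) || is.null(series$duration)) {
    stop("`series` must be an event_series with fields times and duration")
  }
  duration <- series$duration
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number of seconds")
  }
  times <- as.numeric(series$times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("event times must be finite and non-missing")
  }
  bad <- times < 0 | times >= duration
  if (any(bad)) {
    stop(sprintf(
      "event time %g outside [0, %g): all times must lie within the scan",
      times[which(bad)[1]], duration
    ))
  }
  if (is.unsorted(times)) times <- sort(times)
  if (anyDuplicated(times)) {
    warning(sprintf("%d duplicate timestamp(s) retained in '%s'",
                    sum(duplicated(times)), series$label %||% ""))
  }
  series$times <- times
  class(series) <- "event_series"
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of events in a series
#' @param series An `event_series`.
#' @return Integer event count.
#' @export
n_events <- function(series) length(series$times)

#' Mean detection rate of a series
#' @param series An `event_series`.
#' @return Detection rate in events per minute.
#' @export
event_rate <- function(series) n_events(series) / series$duration * 60

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> '%s': %d events in %.1f s (%.3g events/min)\n",
              x$label, n_events(x), x$duration, event_rate(x)))
  invisible(x)
}

#' Scan configuration: volumetric sampling constants
#'
#' Physiological conversion constants tying scan time to blood volume: the
#' instrument samples blood at a fixed volumetric rate (default 50 ul of
#' peripheral blood per minute) and the animal has a total peripheral blood
#' volume (default 2 ml for a ~25 g mouse). The PBV is used only for display
#' as a percent-of-blood-volume label; all calculations are carried in ul.
#'
#' @param sampling_rate Blood volume sampled per minute, in ul/min. Default 50.
#' @param pbv Total peripheral blood volume in ml. Default 2.
#' @return An object of class `scan_config`.
#' @examples
#' cfg <- scan_config()
#' interval_to_volume(24, cfg)   # 20 ul
#' @export
scan_config <- function(sampling_rate = 50, pbv = 2) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive value (ul/min)")
  }
  if (!is.numeric(pbv) || length(pbv) != 1L || pbv <= 0) {
    stop("`pbv` must be a single positive value (ml)")
  }
  structure(list(sampling_rate = sampling_rate, pbv = pbv),
            class = "scan_config")
}

#' Convert a detection rate to a blood concentration
#'
#' A detection rate of `r` events per minute at a volumetric sampling rate of
#' `sampling_rate` ul/min corresponds to `r / (sampling_rate / 1000)` cells per
#' ml of blood. E.g. 0.019 events/min at 50 ul/min is 0.38 cells/ml.
#'
#' @param rate Detection rate in events per minute, non-negative.
#' @param config A [scan_config()].
#' @return Concentration in events per ml of blood.
#' @export
rate_to_concentration <- function(rate, config = scan_config()) {
  if (any(rate < 0)) stop("`rate` must be non-negative (events/min)")
  rate / (config$sampling_rate / 1000)
}

#' Convert a blood concentration to a detection rate
#'
#' Inverse of [rate_to_concentration()].
#'
#' @param concentration Cells per ml of blood, non-negative.
#' @param config A [scan_config()].
#' @return Detection rate in events per minute.
#' @export
concentration_to_rate <- function(concentration, config = scan_config()) {
  if (any(concentration < 0)) stop("`concentration` must be non-negative")
  concentration * (config$sampling_rate / 1000)
}

#' Equivalent blood volume of a scan interval
#'
#' Maps a scan-time interval to the blood volume sampled during it: a 24 s
#' interval at 50 ul/min corresponds to 20 ul of blood.
#'
#' @param window Interval length in seconds, strictly positive.
#' @param config A [scan_config()].
#' @return Equivalent blood volume in ul.
#' @export
interval_to_volume <- function(window, config = scan_config()) {
  if (any(window <= 0)) stop("`window` must be positive (seconds)")
  window / 60 * config$sampling_rate
}

#' Blood volume as a fraction of total peripheral blood volume
#'
#' Display-layer conversion: 20 ul of a 2 ml PBV is 0.01 (about 1% of the
#' PBV). The fraction is approximate by construction and is not used in any
#' downstream calculation.
#'
#' @param volume Blood volume in ul, non-negative.
#' @param config A [scan_config()].
#' @return Dimensionless fraction of the peripheral blood volume.
#' @export
volume_to_pbv_fraction <- function(volume, config = scan_config()) {
  if (any(volume < 0)) stop("`volume` must be non-negative (ul)")
  volume / (config$pbv * 1000)
}

#' Interval (window) specification
#'
#' Describes a family of equal-length windows laid over a scan: `sliding`
#' windows advance by `stride` seconds (default 1 s), `nonoverlapping`
#' windows tile the scan (`stride == window`). Windows are half-open
#' `[t, t + window)` and trailing partial windows are discarded, matching
#' fixed-size equivalent blood samples.
#'
#' @param window Window length in seconds, strictly positive.
#' @param stride Step between window starts in seconds; defaults to 1 for
#'   sliding mode and to `window` for nonoverlapping mode.
#' @param mode `"sliding"` or `"nonoverlapping"`.
#' @return An object of class `interval_spec`.
#' @export
interval_spec <- function(window, stride = NULL,
                          mode = c("sliding", "nonoverlapping")) {
  mode <- match.arg(mode)
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("`window` must be a single positive number of seconds")
  }
  if (is.null(stride)) stride <- if (mode == "nonoverlapping") window else 1
  if (!is.numeric(stride) || length(stride) != 1L || stride <= 0) {
    stop("`stride` must be a single positive number of seconds")
  }
  if (mode == "nonoverlapping" && stride != window) {
    stop("nonoverlapping mode requires stride == window")
  }
  structure(list(window = window, stride = stride, mode = mode),
            class = "interval_spec")
}

# ---- event-series file format -----------------------------------------------
# CSV with header scan_id,time_s plus a JSON sidecar (<stem>.json) carrying
# duration_s, label and any extra metadata. Times are written with 17
# significant digits so the round trip is lossless.

#' Write an event series to disk
#'
#' Writes `<path>` as CSV (`scan_id,time_s`) and `<path stem>.json` as a JSON
#' sidecar holding `duration_s` and `label`. The pair round-trips losslessly
#' through [read_event_series()].
#'
#' @param series An `event_series`.
#' @param path CSV file path (the sidecar replaces the extension with .json).
#' @param meta Optional named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_event_series <- function(series, path, meta = list()) {
  series <- validate_event_series(series)
  df <- data.frame(
    scan_id = rep(series$label, n_events(series)),
    time_s = sprintf("%.17g", series$times),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  sidecar <- c(list(duration_s = series$duration, label = series$label), meta)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an event series from disk
#'
#' @param path CSV file path written by [write_event_series()].
#' @return An `event_series`.
#' @export
read_event_series <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_series(as.numeric(df$time_s), duration = as.numeric(meta$duration_s),
               label = as.character(meta$label %||% ""))
}

sidecar_path <- function(path) sub("\\.[A-Za-z0-9]+$", ".json", path)
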