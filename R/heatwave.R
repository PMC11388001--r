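#' Station-climatology heatwave threshold
#'
#' Averages daily-maximum temperature across stations day by day, then takes
#' the mean over all days falling in the given season (June-July-August by
#' default) and years.  Applied to a 30-year Houston station record this
#' procedure yields a threshold near 32.1 degC.
#'
#' @param series a station-series data.frame with columns `station_id`,
#'   `date` (Date), `tmax_c`, or a list of single-station data.frames.
#' @param years optional integer vector restricting the climatology years.
#' @param months season months, default `6:8` (JJA).
#' @param max_missing_frac tolerated fraction of season days on which no
#'   station reports; beyond it the climatology is considered unreliable and
#'   an error is raised.  Default 0 (fail-fast).
#' @return the threshold temperature in degC.
#' @export
climatological_threshold <- function(series, years = NULL, months = 6:8,
                                     max_missing_frac = 0) {
  series <- .as_station_frame(series)
  if (length(months) == 0L) stop("'months' must be non-empty")
  keep <- as.integer(format(series$date, "%m")) %in% months
  if (!is.null(years))
    keep <- keep & as.integer(format(series$date, "%Y")) %in% years
  s <- series[keep, , drop = FALSE]
  if (nrow(s) == 0L) stop("no observations in the requested season/years")
  daily <- tapply(s$tmax_c, s$date, mean)
  span <- seq(min(s$date), max(s$date), by = "day")
  span <- span[as.integer(format(span, "%m")) %in% months]
  missing_frac <- 1 - length(daily) / length(span)
  if (missing_frac > max_missing_frac + 1e-12)
    stop(sprintf("%.1f%% of season days missing exceeds tolerance %.1f%%",
                 100 * missing_frac, 100 * max_missing_frac))
  mean(daily)
}

.as_station_frame <- function(series) {
  if (is.list(series) && !is.data.frame(series))
    series <- do.call(rbind, series)
  stopifnot(is.data.frame(series),
            all(c("station_id", "date", "tmax_c") %in% names(series)))
  if (!inherits(series$date, "Date")) series$date <- as.Date(series$date)
  if (anyNA(series$tmax_c) || any(!is.finite(series$tmax_c)))
    stop("'tmax_c' must be finite")
  series
}

#' Detect heat episodes from a station-averaged daily maximum series
#'
#' Days with daily maximum strictly above `threshold` are hot days;
#' maximal runs of consecutive hot days are heat episodes; episodes of at
#' least `min_run` days ("extending beyond 5 days" with the default 6) are
#' returned as heatwave events.
#'
#' @param dates contiguous Date vector (strictly increasing by one day).
#' @param tmax station-averaged daily maximum temperature, degC.
#' @param threshold hot-day threshold, degC (exceedance is strict).
#' @param min_run minimum event duration in days (default 6).
#' @return a data.frame of class `heatwave_events` with columns
#'   `start_date`, `end_date`, `duration`, `peak_tmax`, `peak_date`.
#' @export
detect_events <- function(dates, tmax, threshold, min_run = 6L) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  stopifnot(length(dates) == length(tmax), min_run >= 1)
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("'dates' must be a contiguous daily series")
  hot <- tmax > threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  ev <- data.frame(
    start_date = dates[starts[keep]],
    end_date = dates[ends[keep]],
    duration = r$lengths[keep]
  )
  if (nrow(ev) > 0L) {
    pk <- mapply(function(a, b) {
      i <- a:b
      i[which.max(tmax[i])]
    }, starts[keep], ends[keep])
    ev$peak_tmax <- tmax[pk]
    ev$peak_date <- dates[pk]
  } else {
    ev$peak_tmax <- numeric(0)
    ev$peak_date <- as.Date(character(0))
  }
  class(ev) <- c("heatwave_events", "data.frame")
  ev
}

#' Filter heat episodes down to severe heatwave cases
#'
#' Keeps events whose peak daily maximum strictly exceeds `min_peak` (35.1
#' degC by default) and whose duration strictly exceeds `min_duration` (14
#' days by default) -- the cut that reduces a multi-year set of episodes to
#' the few severe events worth simulating.
#'
#' @param events a `heatwave_events` data.frame from [detect_events()].
#' @param min_peak peak-temperature cut, degC (strict).
#' @param min_duration duration cut, days (strict).
#' @return the filtered events, same class.
#' @export
select_severe <- function(events, min_peak = 35.1, min_duration = 14L) {
  stopifnot(is.data.frame(events),
            all(c("peak_tmax", "duration") %in% names(events)))
  out <- events[events$peak_tmax > min_peak & events$duration > min_duration,
                , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' World Meteorological Organization heatwave check
#'
#' TRUE if and only if the daily-maximum series contains a run of more than
#' `min_run - 1` consecutive days (i.e. at least `min_run`) on which the
#' daily maximum strictly exceeds the long-term average daily maximum by more
#' than `delta` K.  With Houston's 25.6 degC average daily maximum and the
#' default 5 K margin, the exceedance level is 30.6 degC.
#'
#' @param event_window_tmax daily maximum temperatures over the window, degC.
#' @param avg_daily_max long-term average daily maximum, degC.
#' @param delta exceedance margin, K (default 5).
#' @param min_run minimum qualifying run length, days (default 6, i.e.
#'   "more than 5 consecutive days").
#' @return logical flag.
#' @export
wmo_check <- function(event_window_tmax, avg_daily_max, delta = 5,
                      min_run = 6L) {
  hot <- event_window_tmax > avg_daily_max + delta
  r <- rle(hot)
  any(r$values & r$lengths >= min_run)
}

#' Simulation window around a heatwave peak
#'
#' The simulation covers 48 hours on either side of the event's peak hour
#' (21Z by default, 15:00 Central Standard Time for Houston).
#'
#' @param event a one-row `heatwave_events` data.frame, or a Date giving
#'   the peak day directly.
#' @param peak_hour_utc hour of the diurnal peak, UTC (default 21).
#' @param half_width_h half-width of the window in hours (default 48).
#' @return a list with POSIXct `window_start` and `window_end` (UTC).
#' @export
simulation_window <- function(event, peak_hour_utc = 21L,
                              half_width_h = 48L) {
  peak_date <- if (is.data.frame(event)) {
    stopifnot(nrow(event) == 1L, "peak_date" %in% names(event))
    event$peak_date
  } else as.Date(event)
  peak <- as.POSIXct(paste0(format(peak_date, "%Y-%m-%d"), " ",
                            sprintf("%02d:00:00", peak_hour_utc)),
                     tz = "UTC")
  list(window_start = peak - half_width_h * 3600,
       window_end = peak + half_width_h * 3600)
}

#' @export
print.heatwave_events <- function(x, ...) {
  cat("Heatwave events:", nrow(x), "\n")
  if (nrow(x) > 0L) {
    df <- data.frame(start = format(x$start_date), end = format(x$end_date),
                     days = x$duration,
                     peak = sprintf("%.1f degC on %s", x$peak_tmax,
                                    format(x$peak_date)))
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Write heatwave events as JSON lines
#'
#' One JSON object per event with start, end, duration, peak and the
#' simulation window, suitable for machine consumption downstream.
#'
#' @param events a `heatwave_events` data.frame.
#' @param path output file path.
#' @inheritParams simulation_window
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path, peak_hour_utc = 21L,
                               half_width_h = 48L) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    w <- simulation_window(events[i, , drop = FALSE], peak_hour_utc,
                           half_width_h)
    jsonlite::toJSON(list(
      start = format(events$start_date[i]), end = format(events$end_date[i]),
      duration = events$duration[i], peak_tmax = events$peak_tmax[i],
      peak_date = format(events$peak_date[i]),
      window_start = format(w$window_start, "%Y-%m-%dT%H:%MZ"),
      window_end = format(w$window_end, "%Y-%m-%dT%H:%MZ")),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
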