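# Fixed-threshold marine heatwave detection and per-season metrics.
#
# The operational definition used throughout: a marine heatwave is a run of
# at least `min_event_days` consecutive days with daily temperature strictly
# above `threshold_c`, evaluated within the May-September warm season. This
# is the regional fixed-threshold adaptation of the event-based MHW
# definition (the climatological-percentile definition is out of scope).

#' Marine heatwave definition
#'
#' @param threshold_c exceedance threshold in degrees C; a day counts only if
#'   strictly above this value (default 24)
#' @param min_event_days minimum consecutive exceedance days for an event
#'   (default 5)
#' @param season_start,season_end season window as `"MM-DD"` strings
#'   (defaults May 1 to Sep 30)
#' @return object of class `mhw_definition`
#' @export
mhw_definition <- function(threshold_c = 24, min_event_days = 5L,
                           season_start = "05-01", season_end = "09-30") {
  stopifnot(is.finite(threshold_c), min_event_days >= 1)
  if (season_start >= season_end) stop_mesa("season_start must precede season_end")
  structure(list(threshold_c = threshold_c,
                 min_event_days = as.integer(min_event_days),
                 season_start = season_start, season_end = season_end),
            class = "mhw_definition")
}

#' One pixel's daily temperature trace
#'
#' @param dates consecutive calendar `Date`s (no gaps)
#' @param temps_c daily temperature in degrees C; NA marks missing days
#' @param pixel_id identifier carried through the metrics table
#' @return object of class `daily_series`
#' @export
daily_series <- function(dates, temps_c, pixel_id = "px") {
  dates <- as.Date(dates)
  if (length(dates) != length(temps_c)) stop_mesa("dates and temps_c lengths differ")
  if (length(dates) > 1 && any(as.integer(diff(dates)) != 1L)) {
    stop_mesa("daily_series dates must be consecutive days")
  }
  if (any(!is.na(temps_c) & !is.finite(temps_c))) {
    stop_mesa("temps_c must be finite or NA")
  }
  structure(list(dates = dates, temps_c = as.numeric(temps_c),
                 pixel_id = pixel_id),
            class = "daily_series")
}

#' Extract one warm season from a daily series
#'
#' Returns exactly the season window (by default May 1 to Sep 30, 153 days)
#' of the requested year; errors if any day of the window is absent from the
#' series.
#'
#' @param series a [daily_series()]
#' @param year calendar year
#' @param defn a [mhw_definition()]
#' @return a [daily_series()] covering the season
#' @export
extract_season <- function(series, year, defn = mhw_definition()) {
  stopifnot(inherits(series, "daily_series"))
  d0 <- as.Date(sprintf("%d-%s", year, defn$season_start))
  d1 <- as.Date(sprintf("%d-%s", year, defn$season_end))
  want <- seq(d0, d1, by = "day")
  idx <- match(want, series$dates)
  if (anyNA(idx)) {
    miss <- want[is.na(idx)]
    stop_mesa("series does not cover the ", year, " season: missing ",
              format(min(miss)), " .. ", format(max(miss)))
  }
  daily_series(want, series$temps_c[idx], series$pixel_id)
}

# logical exceedance vector; masked days count as below threshold
exceedance_flags <- function(series, defn, warn_masked = TRUE) {
  above <- series$temps_c > defn$threshold_c
  if (anyNA(above)) {
    if (warn_masked) {
      warn_mesa(series$pixel_id, ": ", sum(is.na(above)),
                " masked day(s) treated as below threshold")
    }
    above[is.na(above)] <- FALSE
  }
  above
}

#' Detect marine heatwave events in a daily series
#'
#' Finds maximal runs of days strictly above the threshold; runs of at least
#' `min_event_days` become events, returned in chronological order. Masked
#' (NA) days break runs and are treated as below threshold, with a warning.
#'
#' @param series a [daily_series()] (gap-free)
#' @param defn a [mhw_definition()]
#' @return data.frame: `start_date`, `end_date`, `duration_days`, `peak_c`
#' @examples
#' s <- daily_series(as.Date("2046-05-01") + 0:19,
#'                   c(rep(20, 5), rep(25, 10), rep(20, 5)))
#' detect_events(s)  # one 10-day event
#' @export
detect_events <- function(series, defn = mhw_definition()) {
  stopifnot(inherits(series, "daily_series"))
  above <- exceedance_flags(series, defn)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- which(r$values & r$lengths >= defn$min_event_days)
  data.frame(
    start_date = series$dates[starts[ev]],
    end_date = series$dates[ends[ev]],
    duration_days = r$lengths[ev],
    peak_c = vapply(ev, function(k)
      max(series$temps_c[starts[k]:ends[k]], na.rm = TRUE), numeric(1))
  )
}

#' Per-season susceptibility metrics for one pixel
#'
#' Extracts the four drivers of the susceptibility score from one extracted
#' season:
#' * `max_sst_c` — maximum daily temperature;
#' * `max_run_days` — length of the longest strict-exceedance run, counted
#'   even when shorter than the event minimum;
#' * `n_events` — number of heatwave events ([detect_events()]);
#' * `max_gap_days` — longest run of at-or-below-threshold days lying
#'   strictly between two events; with fewer than two events it is the
#'   longest sub-threshold run anywhere in the season (a season with no
#'   exceedance at all therefore yields the full season length).
#'
#' @param series one extracted season ([extract_season()])
#' @param defn a [mhw_definition()]
#' @return one-row data.frame: `pixel_id`, `year`, `max_sst_c`,
#'   `max_run_days`, `n_events`, `max_gap_days`, `frac_missing`
#' @export
season_metrics <- function(series, defn = mhw_definition()) {
  stopifnot(inherits(series, "daily_series"))
  n <- length(series$dates)
  if (n == 0) stop_mesa("empty series")
  frac_missing <- mean(is.na(series$temps_c))
  if (all(is.na(series$temps_c))) stop_mesa("season is entirely masked")
  above <- exceedance_flags(series, defn, warn_masked = FALSE)
  if (frac_missing > 0) {
    warn_mesa(series$pixel_id, ": ", round(100 * frac_missing),
              "% of season days masked",
      if (frac_missing > 0.1) " (pixel flagged unreliable)" else "")
  }
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  max_run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  ev <- which(r$values & r$lengths >= defn$min_event_days)

  below_len <- r$lengths[!r$values]
  if (length(ev) >= 2) {
    lo <- ends[ev[1]]; hi <- starts[ev[length(ev)]]
    between <- which(!r$values & starts > lo & ends < hi)
    max_gap <- if (length(between)) max(r$lengths[between]) else 0L
  } else {
    max_gap <- if (length(below_len)) max(below_len) else 0L
  }
  data.frame(
    pixel_id = series$pixel_id,
    year = as.integer(format(series$dates[1], "%Y")),
    max_sst_c = max(series$temps_c, na.rm = TRUE),
    max_run_days = as.integer(max_run),
    n_events = length(ev),
    max_gap_days = as.integer(max_gap),
    frac_missing = frac_missing,
    stringsAsFactors = FALSE
  )
}

#' Study period over which seasonal metrics are aggregated
#'
#' @param years integer years (default 2046-2055, centred on 2050)
#' @param aggregation `"mean_metrics"` (average each metric over the years,
#'   then score once — the default) or `"mean_scores"` (score each year,
#'   average the scores)
#' @return object of class `study_period`
#' @export
study_period <- function(years = 2046:2055,
                         aggregation = c("mean_metrics", "mean_scores")) {
  years <- as.integer(years)
  if (length(years) == 0 || is.unsorted(years, strictly = TRUE)) {
    stop_mesa("years must be non-empty and strictly increasing")
  }
  structure(list(years = years, aggregation = match.arg(aggregation)),
            class = "study_period")
}

#' Aggregate yearly season metrics over a study period
#'
#' Under `mean_metrics`, each metric field is averaged arithmetically across
#' the period's years (results may be fractional); the `year` field is set
#' to the period midpoint.
#'
#' @param yearly data.frame of [season_metrics()] rows, one per year of the
#'   period (a single pixel)
#' @param period a [study_period()]
#' @return one-row data.frame with averaged metric fields
#' @export
aggregate_metrics <- function(yearly, period = study_period()) {
  stopifnot(is.data.frame(yearly), inherits(period, "study_period"))
  missing <- setdiff(period$years, yearly$year)
  if (length(missing) > 0) {
    stop_mesa("metrics missing for year(s): ", paste(missing, collapse = ", "))
  }
  yearly <- yearly[yearly$year %in% period$years, , drop = FALSE]
  data.frame(
    pixel_id = yearly$pixel_id[1],
    year = mean(period$years),
    max_sst_c = mean(yearly$max_sst_c),
    max_run_days = mean(yearly$max_run_days),
    n_events = mean(yearly$n_events),
    max_gap_days = mean(yearly$max_gap_days),
    frac_missing = mean(yearly$frac_missing),
    stringsAsFactors = FALSE
  )
}

#' Per-pixel season metrics for every selected pixel and study year
#'
#' @param cube a `raster_cube` covering the seasons of all study years
#' @param pixels data.frame with `pixel_id`, `ix`, `iy` (e.g. from
#'   [select_seagrass_pixels()])
#' @param defn a [mhw_definition()]
#' @param period a [study_period()]
#' @param aggregate if TRUE (default) return one aggregated row per pixel,
#'   otherwise one row per pixel and year
#' @return data.frame of metrics rows
#' @export
cube_season_metrics <- function(cube, pixels, defn = mhw_definition(),
                                period = study_period(), aggregate = TRUE) {
  stopifnot(inherits(cube, "raster_cube"))
  rows <- lapply(seq_len(nrow(pixels)), function(k) {
    s <- cube_series(cube, pixels$ix[k], pixels$iy[k])
    yearly <- do.call(rbind, lapply(period$years, function(y)
      season_metrics(extract_season(s, y, defn), defn)))
    if (aggregate) aggregate_metrics(yearly, period) else yearly
  })
  do.call(rbind, rows)
}
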