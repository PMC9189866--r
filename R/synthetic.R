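# Synthetic inputs with planted, recoverable structure: temperature cubes
# with known heatwave events over a seasonal baseline, toy coastal geography
# partitioned into EEZ bands, and catch/coastline-risk tables with controlled
# country shares. Every generator is deterministic under the config seed, so
# the full pipeline can be exercised and asserted against ground truth
# without any external download.

#' Event specification for planted heatwaves
#'
#' @param start_day season-relative start day (1 = first season day)
#' @param duration_days event length in days
#' @param peak_c peak temperature in degrees C, reached at the event midpoint
#' @return data.frame of event specs
#' @export
event_spec <- function(start_day, duration_days, peak_c) {
  data.frame(start_day = as.integer(start_day),
             duration_days = as.integer(duration_days),
             peak_c = peak_c)
}

#' Synthetic-data configuration
#'
#' Defaults describe the study conditions the pipeline is built for: a
#' 1 x 1 degree box gridded at 0.1 degrees (matching the temperature-product
#' resolution), study years 2046-2055, a seasonal baseline peaking in August
#' below the 24 degree heat-stress threshold (so zero-event pixels are
#' constructible), three countries, and catch shares / coastline-risk
#' percentages spanning all three importance classes.
#'
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` (default 10-11 E,
#'   35-36 N)
#' @param n_lon,n_lat pixels per axis (default 10 x 10, i.e. 0.1 degrees)
#' @param years study years (default 2046-2055)
#' @param baseline_mean_c annual-mean baseline temperature (default 22)
#' @param baseline_amp_c seasonal amplitude (default 1.5; August peak 23.5,
#'   strictly below the threshold)
#' @param noise_sd_c daily Gaussian noise SD (default 0: exact-recovery mode)
#' @param guard_c guard band around the threshold that clipped noise may not
#'   cross (default 0.5)
#' @param threshold_c heatwave threshold the events are planted against
#' @param events NULL (no events), a single [event_spec()] data.frame applied
#'   to every pixel and year, or a function `(ix, iy, year) -> event specs`
#' @param n_countries number of longitudinal EEZ bands (default 3)
#' @param catch_shares per-country catch shares in percent, summing to 100
#'   (default 50/30/20)
#' @param risk_pcts per-country percent of coastline at very-high hazard
#'   risk (default 30/10/1, one country per importance class)
#' @param seed integer seed fixing all randomness
#' @return object of class `synth_config`
#' @export
synth_config <- function(bbox = c(10, 11, 35, 36), n_lon = 10, n_lat = 10,
                         years = 2046:2055, baseline_mean_c = 22,
                         baseline_amp_c = 1.5, noise_sd_c = 0, guard_c = 0.5,
                         threshold_c = 24, events = NULL, n_countries = 3,
                         catch_shares = c(50, 30, 20),
                         risk_pcts = c(30, 10, 1), seed = 1L) {
  stopifnot(length(bbox) == 4, bbox[1] < bbox[2], bbox[3] < bbox[4],
            n_lon >= 1, n_lat >= 1, noise_sd_c >= 0, guard_c > 0,
            n_countries >= 1)
  if (length(catch_shares) != n_countries || length(risk_pcts) != n_countries) {
    stop_mesa("catch_shares and risk_pcts must have one entry per country")
  }
  if (abs(sum(catch_shares) - 100) > 1e-9) {
    stop_mesa("catch_shares must sum to 100, got ", sum(catch_shares))
  }
  if (any(risk_pcts < 0 | risk_pcts > 100)) stop_mesa("risk_pcts must lie in [0, 100]")
  if (baseline_mean_c + baseline_amp_c >= threshold_c) {
    stop_mesa("baseline must stay strictly below the threshold")
  }
  structure(list(bbox = bbox, n_lon = n_lon, n_lat = n_lat, years = years,
                 baseline_mean_c = baseline_mean_c,
                 baseline_amp_c = baseline_amp_c, noise_sd_c = noise_sd_c,
                 guard_c = guard_c, threshold_c = threshold_c, events = events,
                 n_countries = n_countries, catch_shares = catch_shares,
                 risk_pcts = risk_pcts, seed = as.integer(seed)),
            class = "synth_config")
}

country_codes <- function(n) sprintf("C%02d", seq_len(n))

# annual sinusoidal baseline peaking mid-August (day of year 227)
baseline_temps <- function(dates, mean_c, amp_c) {
  doy <- as.integer(format(dates, "%j"))
  mean_c + amp_c * cos(2 * pi * (doy - 227) / 365.25)
}

#' Plant heatwave events into a below-threshold baseline series
#'
#' Each event replaces its days with a tent shape rising from
#' `threshold + guard` at the edges to `peak_c` at the midpoint, so the
#' planted (max SST, run length, event count, inter-event gap) are exactly
#' recoverable by the metrics stage. Gaussian noise, when requested, is
#' clipped so it never crosses the threshold guard band (non-event days stay
#' at or below `threshold - guard`, event days within
#' `[threshold + guard, peak]`, and the midpoint keeps the exact peak).
#'
#' @param baseline a [daily_series()] strictly below `threshold_c` everywhere
#' @param events an [event_spec()] data.frame, days relative to the series
#'   start; events must not overlap and must be separated by at least one day
#' @param noise_sd_c Gaussian noise SD in degrees C (0 = noise-free)
#' @param seed integer seed (required when `noise_sd_c > 0`)
#' @param threshold_c heatwave threshold
#' @param guard_c guard band width
#' @return a [daily_series()]
#' @export
plant_event_series <- function(baseline, events = NULL, noise_sd_c = 0,
                               seed = NULL, threshold_c = 24, guard_c = 0.5) {
  stopifnot(inherits(baseline, "daily_series"))
  n <- length(baseline$dates)
  temps <- baseline$temps_c
  if (any(temps >= threshold_c)) {
    stop_mesa("baseline must be strictly below the threshold on all days")
  }
  in_event <- rep(FALSE, n)
  base_lvl <- threshold_c + guard_c
  if (!is.null(events) && nrow(events) > 0) {
    events <- events[order(events$start_day), , drop = FALSE]
    ends <- events$start_day + events$duration_days - 1
    if (any(events$start_day < 1) || any(ends > n)) {
      stop_mesa("event extends outside the series")
    }
    if (nrow(events) > 1 && any(events$start_day[-1] <= ends[-nrow(events)] + 1)) {
      stop_mesa("events overlap or are not separated by at least one day")
    }
    if (any(events$peak_c < base_lvl)) {
      stop_mesa("event peak_c must be at least threshold + guard")
    }
    for (k in seq_len(nrow(events))) {
      days <- events$start_day[k]:ends[k]
      mid <- days[ceiling(length(days) / 2)]
      half <- max(mid - days[1], days[length(days)] - mid, 1)
      shape <- base_lvl + (events$peak_c[k] - base_lvl) * (1 - abs(days - mid) / half)
      if (length(days) == 1) shape <- events$peak_c[k]
      shape[days == mid] <- events$peak_c[k]
      temps[days] <- pmax(temps[days], shape)
      in_event[days] <- TRUE
    }
  }
  if (noise_sd_c > 0) {
    if (is.null(seed)) stop_mesa("a seed is required when noise_sd_c > 0")
    set.seed(seed)
    nz <- stats::rnorm(n, 0, noise_sd_c)
    out <- temps + nz
    out[!in_event] <- pmin(out[!in_event], threshold_c - guard_c)
    out[in_event] <- pmin(pmax(out[in_event], base_lvl), temps[in_event])
    # keep each event peak exact so max SST is recoverable
    if (!is.null(events) && nrow(events) > 0) {
      for (k in seq_len(nrow(events))) {
        days <- events$start_day[k]:(events$start_day[k] + events$duration_days[k] - 1)
        mid <- days[ceiling(length(days) / 2)]
        out[mid] <- events$peak_c[k]
      }
    }
    temps <- out
  }
  daily_series(baseline$dates, temps, baseline$pixel_id)
}

resolve_events <- function(config, ix, iy, year) {
  ev <- config$events
  if (is.null(ev)) return(NULL)
  if (is.function(ev)) return(ev(ix, iy, year))
  ev
}

#' Generate a synthetic daily temperature cube
#'
#' Builds a continuous daily cube over the full study years (so the seasonal
#' extraction step is exercised), with each pixel's May-September window
#' carrying the events resolved from the config. Values are in degrees C
#' in memory; [write_sst_cube()] serializes in Kelvin to exercise the ingest
#' conversion.
#'
#' @param config a [synth_config()]
#' @return a [raster_cube()]
#' @export
synth_sst_cube <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  lon_edges <- seq(config$bbox[1], config$bbox[2], length.out = config$n_lon + 1)
  lat_edges <- seq(config$bbox[3], config$bbox[4], length.out = config$n_lat + 1)
  base <- baseline_temps(dates, config$baseline_mean_c, config$baseline_amp_c)
  vals <- array(NA_real_, c(length(dates), config$n_lat, config$n_lon))
  defn <- mhw_definition(threshold_c = config$threshold_c)
  for (ix in seq_len(config$n_lon)) {
    for (iy in seq_len(config$n_lat)) {
      temps <- base
      for (year in config$years) {
        d0 <- as.Date(sprintf("%d-%s", year, defn$season_start))
        d1 <- as.Date(sprintf("%d-%s", year, defn$season_end))
        idx <- which(dates >= d0 & dates <= d1)
        season <- daily_series(dates[idx], base[idx],
                               sprintf("px%03d_%03d", ix, iy))
        planted <- plant_event_series(
          season, resolve_events(config, ix, iy, year),
          noise_sd_c = config$noise_sd_c,
          seed = config$seed + ix * 10000L + iy * 100L + (year %% 100L),
          threshold_c = config$threshold_c, guard_c = config$guard_c)
        temps[idx] <- planted$temps_c
      }
      vals[, iy, ix] <- temps
    }
  }
  raster_cube(lon_edges, lat_edges, dates, vals)
}

#' Generate toy coastal geography with known ground truth
#'
#' Partitions the config bbox into `n_countries` equal longitudinal EEZ
#' bands and places one small seagrass patch per country, wholly inside a
#' known pixel near the southern ("coastal") edge of its band. The returned
#' truth table makes patch-to-pixel and cell-to-country assignments
#' assertable.
#'
#' @param config a [synth_config()]
#' @return list: `patches` ([seagrass_patches()]), `eez` ([eez_map()]),
#'   `truth` data.frame (`country_code`, `ix`, `iy`, patch center coords)
#' @export
synth_geography <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_countries > config$n_lon) {
    stop_mesa("n_countries exceeds the number of pixel columns")
  }
  codes <- country_codes(config$n_countries)
  band_edges <- seq(config$bbox[1], config$bbox[2],
                    length.out = config$n_countries + 1)
  eez_polys <- lapply(seq_len(config$n_countries), function(k) {
    rbind(c(band_edges[k], config$bbox[3]), c(band_edges[k + 1], config$bbox[3]),
          c(band_edges[k + 1], config$bbox[4]), c(band_edges[k], config$bbox[4]))
  })
  names(eez_polys) <- codes

  dlon <- (config$bbox[2] - config$bbox[1]) / config$n_lon
  dlat <- (config$bbox[4] - config$bbox[3]) / config$n_lat
  truth <- do.call(rbind, lapply(seq_len(config$n_countries), function(k) {
    band_mid <- (band_edges[k] + band_edges[k + 1]) / 2
    ix <- min(config$n_lon, max(1, ceiling((band_mid - config$bbox[1]) / dlon)))
    iy <- min(2L, config$n_lat)
    data.frame(country_code = codes[k], ix = ix, iy = iy,
               lon = config$bbox[1] + (ix - 0.5) * dlon,
               lat = config$bbox[3] + (iy - 0.5) * dlat,
               stringsAsFactors = FALSE)
  }))
  patches <- lapply(seq_len(nrow(truth)), function(k) {
    w <- 0.2 * dlon; h <- 0.2 * dlat
    rbind(c(truth$lon[k] - w, truth$lat[k] - h),
          c(truth$lon[k] + w, truth$lat[k] - h),
          c(truth$lon[k] + w, truth$lat[k] + h),
          c(truth$lon[k] - w, truth$lat[k] + h))
  })
  list(patches = seagrass_patches(patches, source_tag = "synthetic"),
       eez = eez_map(eez_polys), truth = truth)
}

#' Generate a synthetic capture-production table
#'
#' Tonnage is distributed over the default taxa so that the pooled means
#' over the reference years reproduce the configured country shares exactly:
#' per-year deviations are mean-zero across the years by construction.
#'
#' @param config a [synth_config()]
#' @param years reference years (default 2014-2018)
#' @param total_tonnes regional pooled total (default 1000)
#' @return data.frame: `country_code`, `taxon`, `year`, `tonnes`
#' @export
synth_catch_table <- function(config, years = 2014:2018, total_tonnes = 1000) {
  stopifnot(inherits(config, "synth_config"))
  codes <- country_codes(config$n_countries)
  species <- unlist(default_taxa(), use.names = FALSE)
  ny <- length(years)
  set.seed(config$seed)
  rows <- list()
  for (k in seq_along(codes)) {
    base <- config$catch_shares[k] / 100 * total_tonnes / length(species)
    for (s in species) {
      dev <- pmin(pmax(stats::rnorm(ny, 0, 0.1), -0.4), 0.4)
      dev <- dev - mean(dev)  # mean-zero across years, exactly; |dev| < 1
      tons <- base * (1 + dev)
      rows[[length(rows) + 1]] <- data.frame(
        country_code = codes[k], taxon = s, year = years, tonnes = tons,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic coastline-risk table
#'
#' @param config a [synth_config()]
#' @return data.frame: `country_code`, `pct_very_high_risk`
#' @export
synth_risk_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  data.frame(country_code = country_codes(config$n_countries),
             pct_very_high_risk = config$risk_pcts,
             stringsAsFactors = FALSE)
}
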