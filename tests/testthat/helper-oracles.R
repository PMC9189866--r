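# Independent oracles and fixture builders shared across the suite.

season_dates <- function(year = 2046) {
  seq(as.Date(sprintf("%d-05-01", year)), as.Date(sprintf("%d-09-30", year)),
      by = "day")
}

# Brute-force day-by-day run scanner: the independent oracle for
# detect_events. Walks the series once, accumulating strict-exceedance runs.
bf_detect <- function(temps, threshold = 24, min_days = 5) {
  starts <- integer(0); durs <- integer(0)
  run <- 0L
  for (i in seq_along(temps)) {
    above <- !is.na(temps[i]) && temps[i] > threshold
    if (above) {
      run <- run + 1L
    } else {
      if (run >= min_days) {
        starts <- c(starts, i - run); durs <- c(durs, run)
      }
      run <- 0L
    }
  }
  if (run >= min_days) {
    starts <- c(starts, length(temps) - run + 1L); durs <- c(durs, run)
  }
  data.frame(start = starts, duration = durs)
}

# Independent restatement of the five-class factor tables as if/else chains,
# used as the oracle for the table-driven scorer.
oracle_factor <- function(value, factor) {
  switch(factor,
    max_sst = if (value < 24) 1 else if (value < 27) 2 else if (value < 29) 3
              else if (value < 32) 4 else 5,
    max_duration = if (value <= 4) 1 else if (value <= 10) 2
                   else if (value <= 20) 3 else if (value <= 30) 4 else 5,
    n_events = if (value == 0) 1 else if (value == 1) 2 else if (value == 2) 3
               else if (value == 3) 4 else 5,
    gap = if (value >= 60) 1 else if (value >= 40) 2 else if (value >= 20) 3
          else if (value >= 5) 4 else 5
  )
}

# A random planted-season layout with its ground-truth metrics, derived
# purely from the layout arithmetic (independent of package functions).
random_layout <- function(max_events = 4) {
  n_ev <- sample(0:max_events, 1)
  starts <- integer(0); durs <- integer(0); peaks <- numeric(0)
  pos <- 1L
  for (k in seq_len(n_ev)) {
    gap <- sample(2:20, 1)
    dur <- sample(5:30, 1)
    if (pos + gap + dur - 1L > 153L) break
    starts <- c(starts, pos + gap)
    durs <- c(durs, dur)
    peaks <- c(peaks, round(runif(1, 25, 33), 2))
    pos <- pos + gap + dur
  }
  n_ev <- length(starts)
  ends <- starts + durs - 1L
  below <- c(if (n_ev > 0) starts[1] - 1L else 153L,
             if (n_ev > 1) starts[-1] - ends[-n_ev] - 1L,
             if (n_ev > 0) 153L - ends[n_ev])
  truth_gap <- if (n_ev >= 2) {
    max(starts[-1] - ends[-n_ev] - 1L)
  } else {
    max(below)
  }
  list(
    events = if (n_ev > 0) event_spec(starts, durs, peaks) else NULL,
    truth = list(n_events = n_ev,
                 max_run = if (n_ev > 0) max(durs) else 0L,
                 max_gap = truth_gap,
                 max_sst = if (n_ev > 0) max(peaks) else NA_real_)
  )
}

flat_baseline <- function(temp = 21, year = 2046, pixel_id = "px") {
  daily_series(season_dates(year), rep(temp, 153), pixel_id)
}

unit_square <- function(x0, y0, w = 1, h = 1) {
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
}
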