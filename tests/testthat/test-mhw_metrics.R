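# Event detection and the four per-season susceptibility metrics.

test_that("extract_season returns exactly the 153-day May-September window", {
  full <- daily_series(seq(as.Date("2046-01-01"), as.Date("2046-12-31"), "day"),
                       rep(20, 365))
  s <- extract_season(full, 2046)
  expect_length(s$dates, 153)
  expect_identical(s$dates[1], as.Date("2046-05-01"))
  expect_identical(s$dates[153], as.Date("2046-09-30"))
  # a season-only series comes back unchanged
  so <- flat_baseline(20)
  expect_identical(extract_season(so, 2046)$temps_c, so$temps_c)
  # missing June is reported as a date range
  holey <- daily_series(seq(as.Date("2046-07-01"), as.Date("2046-12-31"), "day"),
                        rep(20, 184))
  expect_error(extract_season(holey, 2046), "2046-05-01 .. 2046-06-30")
})

test_that("events are maximal strict-exceedance runs of at least five days", {
  s <- flat_baseline(20)
  s$temps_c[11:20] <- 25
  ev <- detect_events(s)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$duration_days, 10L)
  expect_identical(ev$peak_c, 25)

  # 4-day run is not an event; a day at exactly 24.0 is not an exceedance
  s4 <- flat_baseline(20); s4$temps_c[10:13] <- 26
  expect_identical(nrow(detect_events(s4)), 0L)
  s24 <- flat_baseline(20); s24$temps_c[10:20] <- 24
  expect_identical(nrow(detect_events(s24)), 0L)

  # runs of 6, 3 and 7 days -> two events
  s637 <- flat_baseline(20)
  s637$temps_c[10:15] <- 26; s637$temps_c[20:22] <- 26; s637$temps_c[30:36] <- 26
  ev3 <- detect_events(s637)
  expect_identical(ev3$duration_days, c(6L, 7L))
})

test_that("detect_events matches the brute-force scanner on random series", {
  set.seed(42)
  defn <- mhw_definition()
  for (i in 1:300) {
    temps <- 24 + rnorm(153, 0, 1.5)
    s <- daily_series(season_dates(), temps)
    got <- detect_events(s, defn)
    want <- bf_detect(temps)
    expect_identical(got$duration_days, want$duration)
    expect_identical(as.integer(got$start_date - s$dates[1]) + 1L, want$start)
  }
})

test_that("season metrics: degenerate and planted cases", {
  # constant 20 C: no exceedance, gap is the whole season
  m <- season_metrics(flat_baseline(20))
  expect_equal(unlist(m[c("max_sst_c", "max_run_days", "n_events", "max_gap_days")]),
               c(max_sst_c = 20, max_run_days = 0, n_events = 0, max_gap_days = 153))
  # whole season at 28 C: one season-long event, no gap
  m28 <- season_metrics(daily_series(season_dates(), rep(28, 153)))
  expect_equal(unname(unlist(m28[c("max_sst_c", "max_run_days", "n_events", "max_gap_days")])),
               c(28, 153, 1, 0))
  # planted: peaks 29.5, runs 25 and 12 days, 30 sub-threshold days between
  s <- plant_event_series(flat_baseline(21),
                          event_spec(c(10, 65), c(25, 12), c(29.5, 28)))
  mp <- season_metrics(s)
  expect_identical(mp$max_sst_c, 29.5)
  expect_identical(mp$max_run_days, 25L)
  expect_identical(mp$n_events, 2L)
  expect_identical(mp$max_gap_days, 30L)
  expect_error(season_metrics(daily_series(as.Date(character(0)), numeric(0))),
               "empty")
})

test_that("sub-minimum runs count toward max_run_days but not events", {
  s <- flat_baseline(20)
  s$temps_c[10:12] <- 26   # 3-day run
  m <- season_metrics(s)
  expect_identical(m$max_run_days, 3L)
  expect_identical(m$n_events, 0L)
  # with <2 events the gap is the longest sub-threshold run anywhere
  expect_identical(m$max_gap_days, 141L)  # days 13..153
})

test_that("masked days break runs with a warning", {
  s <- flat_baseline(20)
  s$temps_c[10:20] <- 26
  s$temps_c[15] <- NA
  expect_warning(ev <- detect_events(s), "masked")
  expect_identical(ev$duration_days, c(5L, 5L))  # 10:14 and 16:20 survive
})

test_that("padding a season with sub-threshold days leaves events unchanged", {
  set.seed(7)
  for (i in 1:20) {
    lay <- random_layout()
    s <- plant_event_series(flat_baseline(21), lay$events)
    m0 <- season_metrics(s)
    padded <- daily_series(c(s$dates[1] - 1, s$dates, s$dates[153] + 1),
                           c(20, s$temps_c, 20))
    m1 <- season_metrics(padded)
    expect_identical(m1$n_events, m0$n_events)
    expect_identical(m1$max_run_days, m0$max_run_days)
  }
})

test_that("raising a bridging day above threshold can only merge runs, never lose events", {
  s <- flat_baseline(20)
  s$temps_c[10:14] <- 26; s$temps_c[16:20] <- 26  # two 5-day events, day 15 below
  n0 <- nrow(detect_events(s))
  s$temps_c[15] <- 25
  n1 <- nrow(detect_events(s))
  expect_identical(n0, 2L)
  expect_identical(n1, 1L)
  m <- season_metrics(s)
  expect_identical(m$max_run_days, 11L)
})

test_that("aggregation over the study period is the arithmetic mean per field", {
  period <- study_period(2046:2047)
  one <- function(year, n_events, max_sst) {
    data.frame(pixel_id = "px", year = year, max_sst_c = max_sst,
               max_run_days = 10L, n_events = n_events, max_gap_days = 20L,
               frac_missing = 0)
  }
  agg <- aggregate_metrics(rbind(one(2046, 2L, 26), one(2047, 4L, 27)), period)
  expect_identical(agg$n_events, 3)
  expect_identical(agg$max_sst_c, 26.5)
  # idempotence on identical years
  same <- aggregate_metrics(rbind(one(2046, 2L, 26), one(2047, 2L, 26)), period)
  expect_identical(same$n_events, 2)
  # a planted linear ramp 26..29 over ten years averages to 27.5
  p10 <- study_period(2046:2055)
  ramp <- do.call(rbind, lapply(1:10, function(k)
    one(2045 + k, 1L, 26 + 3 * (k - 1) / 9)))
  expect_equal(aggregate_metrics(ramp, p10)$max_sst_c, 27.5)
  expect_error(aggregate_metrics(ramp[-3, ], p10), "2048")
})
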