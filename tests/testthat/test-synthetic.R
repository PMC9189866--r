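# Planted-parameter recovery and determinism of the synthetic generators.

test_that("noise-free planting is exact: no events leaves the baseline unchanged", {
  base <- flat_baseline(21)
  out <- plant_event_series(base, NULL)
  expect_identical(out$temps_c, base$temps_c)
  expect_error(plant_event_series(daily_series(season_dates(), rep(25, 153)), NULL),
               "strictly below")
  expect_error(plant_event_series(base, event_spec(c(10, 15), c(10, 5), c(27, 27))),
               "overlap")
})

test_that("planted events are recovered with their duration, peak, and gap", {
  base <- flat_baseline(21)
  one <- plant_event_series(base, event_spec(20, 10, 28))
  ev <- detect_events(one)
  expect_identical(ev$duration_days, 10L)
  expect_identical(ev$peak_c, 28)
  two <- plant_event_series(base, event_spec(c(10, 47), c(7, 9), c(26, 30)))
  m <- season_metrics(two)
  expect_identical(m$max_gap_days, 30L)
  expect_identical(m$n_events, 2L)
  expect_identical(m$max_sst_c, 30)
})

test_that("full planted-parameter recovery holds across random noise-free layouts", {
  set.seed(101)
  for (i in 1:60) {
    lay <- random_layout()
    s <- plant_event_series(flat_baseline(21), lay$events)
    m <- season_metrics(s)
    expect_identical(m$n_events, lay$truth$n_events)
    expect_identical(m$max_run_days, as.integer(lay$truth$max_run))
    expect_identical(m$max_gap_days, as.integer(lay$truth$max_gap))
    if (lay$truth$n_events > 0) expect_identical(m$max_sst_c, lay$truth$max_sst)
  }
})

test_that("clipped noise never crosses the threshold guard band", {
  base <- flat_baseline(22)
  events <- event_spec(c(15, 60), c(8, 12), c(27, 29))
  noisy <- plant_event_series(base, events, noise_sd_c = 0.8, seed = 9,
                              threshold_c = 24, guard_c = 0.5)
  m <- season_metrics(noisy)
  expect_identical(m$n_events, 2L)
  expect_identical(m$max_run_days, 12L)
  expect_identical(m$max_sst_c, 29)
  in_event <- c(15:22, 60:71)
  expect_true(all(noisy$temps_c[in_event] >= 24.5))
  expect_true(all(noisy$temps_c[-in_event] <= 23.5))
})

test_that("the cube generator is deterministic and uniform specs give identical pixels", {
  cfg <- synth_config(n_lon = 2, n_lat = 2, years = 2046:2047,
                      events = event_spec(c(5, 40), c(6, 8), c(26, 27)),
                      noise_sd_c = 0)
  c1 <- synth_sst_cube(cfg)
  c2 <- synth_sst_cube(cfg)
  expect_identical(c1$values, c2$values)
  expect_identical(c1$values[, 1, 1], c1$values[, 2, 2])
  # with noise, the seed still fixes everything
  cfgN <- synth_config(n_lon = 2, n_lat = 1, years = 2046, noise_sd_c = 0.3,
                       events = event_spec(5, 6, 26), seed = 4L)
  expect_identical(synth_sst_cube(cfgN)$values, synth_sst_cube(cfgN)$values)
})

test_that("synthetic geography returns its own ground truth", {
  cfg <- synth_config(n_countries = 3)
  geo <- synth_geography(cfg)
  expect_identical(names(geo$eez$polygons), c("C01", "C02", "C03"))
  cube <- synth_sst_cube(synth_config(n_countries = 3, years = 2046))
  sel <- select_seagrass_pixels(cube, geo$patches)
  expect_setequal(sel$pixel_id, sprintf("px%03d_%03d", geo$truth$ix, geo$truth$iy))
  # one country: everything maps to it
  geo1 <- synth_geography(synth_config(n_countries = 1, catch_shares = 100,
                                       risk_pcts = 10))
  cells <- generate_qdgc_grid(3, cfg$bbox)
  asg <- assign_cells_to_eez(cells, geo1$eez)
  expect_true(all(asg$country_code == "C01"))
  expect_error(synth_geography(synth_config(n_lon = 2, n_countries = 3,
                                            catch_shares = c(50, 30, 20),
                                            risk_pcts = c(1, 1, 1))),
               "exceeds")
})

test_that("a patch straddling a pixel boundary selects both pixels", {
  cube <- synth_sst_cube(synth_config(n_lon = 10, n_lat = 10, years = 2046))
  straddle <- seagrass_patches(unit_square(10.18, 35.05, 0.05, 0.02))
  sel <- select_seagrass_pixels(cube, straddle)
  expect_setequal(sel$pixel_id, c("px002_001", "px003_001"))
})

test_that("requested catch shares and risk percentages round-trip through scoring", {
  cfg <- synth_config(n_countries = 3, catch_shares = c(50, 30, 20),
                      risk_pcts = c(30, 10, 1))
  catch <- synth_catch_table(cfg)
  sh <- eez_catch_share(catch)
  expect_equal(unname(sh[c("C01", "C02", "C03")]), c(50, 30, 20),
               tolerance = 1e-9)
  risk <- synth_risk_table(cfg)
  hz <- vapply(risk$pct_very_high_risk, score_importance, integer(1))
  expect_identical(hz, c(5L, 3L, 1L))
  # two-country 25/75 split
  cfg2 <- synth_config(n_countries = 2, catch_shares = c(25, 75),
                       risk_pcts = c(0, 0))
  sh2 <- eez_catch_share(synth_catch_table(cfg2))
  expect_equal(unname(sh2[c("C01", "C02")]), c(25, 75), tolerance = 1e-9)
  expect_error(synth_config(n_countries = 2, catch_shares = c(60, 50),
                            risk_pcts = c(0, 0)), "sum to 100")
})
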