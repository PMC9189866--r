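# Factor class tables, impact severity / potential for recovery, and the
# susceptibility combination matrix.

test_that("factor scorers reproduce every class boundary (exhaustive sweep)", {
  eps <- 1e-9
  sst_vals <- c(0, 20, 23.9, 24 - eps, 24, 24 + eps, 26.9, 27 - eps, 27,
                28.9, 29 - eps, 29, 31.9, 32 - eps, 32, 35, 40)
  for (v in sst_vals) {
    expect_identical(score_factor(v, "max_sst"), as.integer(oracle_factor(v, "max_sst")),
                     label = sprintf("max_sst %.10f", v))
  }
  for (d in 0:40) {
    expect_identical(score_factor(d, "max_duration"),
                     as.integer(oracle_factor(d, "max_duration")),
                     label = sprintf("duration %d", d))
  }
  for (n in 0:8) {
    expect_identical(score_factor(n, "n_events"),
                     as.integer(oracle_factor(n, "n_events")),
                     label = sprintf("events %d", n))
  }
  for (g in c(0:65, 100, 153)) {
    expect_identical(score_factor(g, "gap"), as.integer(oracle_factor(g, "gap")),
                     label = sprintf("gap %d", g))
  }
  expect_identical(score_factor(45, "gap"), 2L)
  expect_error(score_factor(-1, "n_events"), "negative")
  expect_error(score_factor(-3, "max_duration"), "negative")
})

test_that("fractional aggregated metrics round half-up before class lookup", {
  expect_identical(score_factor(3.4, "n_events"), 4L)  # rounds to 3
  expect_identical(score_factor(3.5, "n_events"), 5L)  # rounds to 4
  expect_identical(score_factor(20.5, "max_duration"), 4L)  # rounds to 21
  expect_identical(score_factor(4.5, "gap"), 4L)  # rounds to 5
  # max SST is continuous: no rounding
  expect_identical(score_factor(26.6, "max_sst"), 2L)
})

test_that("the susceptibility matrix equals the printed table and its ceil-mean form", {
  m <- susceptibility_matrix()
  printed <- rbind(c(1, 2, 2, 3, 3),
                   c(2, 2, 3, 3, 4),
                   c(2, 3, 3, 4, 4),
                   c(3, 3, 4, 4, 5),
                   c(3, 4, 4, 5, 5))
  expect_identical(unname(m), matrix(as.integer(printed), 5))
  for (a in 1:5) for (b in 1:5) {
    expect_identical(m[a, b], as.integer(ceiling((a + b) / 2)))
  }
  expect_identical(unname(m), unname(t(m)))  # symmetric
  expect_true(all(diff(t(m)) >= 0) && all(diff(m) >= 0))  # monotone rows/cols
})

test_that("impact severity and recovery potential are equal-weight means of factor scores", {
  m <- function(sst, run, ev, gap) {
    data.frame(max_sst_c = sst, max_run_days = run, n_events = ev,
               max_gap_days = gap)
  }
  expect_identical(impact_severity(m(30, 35, 0, 153)), 4.5)
  expect_identical(impact_severity(m(20, 0, 0, 153)), 1)
  expect_identical(impact_severity(m(29.5, 25, 0, 153)), 4)
  expect_identical(recovery_potential(m(20, 0, 0, 153)), 1)
  expect_identical(recovery_potential(m(20, 0, 2, 30)), 3)
  expect_identical(recovery_potential(m(20, 0, 4, 4)), 5)
})

test_that("combining rounds half-up then looks up the matrix", {
  expect_identical(combine_susceptibility(2, 5), 4L)
  expect_identical(combine_susceptibility(1, 1), 1L)
  expect_identical(combine_susceptibility(3.5, 2), 3L)  # (4, 2) -> 3
  expect_error(combine_susceptibility(0.5, 3), "\\[1, 5\\]")
  expect_error(combine_susceptibility(3, 5.5), "\\[1, 5\\]")
})

test_that("susceptibility is monotone in each driver", {
  thr <- default_thresholds()
  base <- data.frame(pixel_id = "px", max_sst_c = 26, max_run_days = 8,
                     n_events = 1, max_gap_days = 45, frac_missing = 0)
  susc_of <- function(m) score_pixels(m, thr)$susceptibility
  # non-decreasing in max SST, duration, events
  for (field in c("max_sst_c", "max_run_days", "n_events")) {
    vals <- seq(0, 40, by = 1)
    out <- vapply(vals, function(v) { m <- base; m[[field]] <- v; susc_of(m) },
                  integer(1))
    expect_true(all(diff(out) >= 0), label = paste("monotone in", field))
  }
  # non-increasing in gap
  gaps <- 0:80
  out <- vapply(gaps, function(g) { m <- base; m$max_gap_days <- g; susc_of(m) },
                integer(1))
  expect_true(all(diff(out) <= 0))
})

test_that("a season that never exceeds 24 C scores susceptibility 1 end to end", {
  s <- flat_baseline(23.2)
  m <- season_metrics(s)
  sc <- score_pixels(m)
  expect_identical(sc$sst_score, 1L)
  expect_identical(sc$impact_severity, 1)
  expect_identical(sc$recovery_potential, 1)
  expect_identical(sc$susceptibility, 1L)
})
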