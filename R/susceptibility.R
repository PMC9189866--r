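# Categorical susceptibility scoring: factor class tables, impact severity,
# potential for recovery, and the 5x5 susceptibility combination matrix.

#' Default factor scoring thresholds
#'
#' The five-class tables mapping each of the four per-pixel metrics onto a
#' 1 (very low) to 5 (very high) susceptibility contribution:
#'
#' | score | max SST (deg C) | max MHW length | events/season | gap between |
#' |-------|-----------------|----------------|---------------|-------------|
#' | 1     | < 24            | <= 4 d         | 0             | >= 60 d     |
#' | 2     | 24 - <27        | 5-10 d         | 1             | 40-59 d     |
#' | 3     | 27 - <29        | 11-20 d        | 2             | 20-39 d     |
#' | 4     | 29 - <32        | 21-30 d        | 3             | 5-19 d      |
#' | 5     | >= 32           | >= 31 d        | >= 4          | < 5 d       |
#'
#' Max SST is scored on the continuous value; the day/count factors are
#' integer classes, so fractional aggregated metrics are rounded half-up
#' before lookup. The duration rows as printed overlap at 20 days; here 20
#' days scores 3 (bins <=4, 5-10, 11-20, 21-30, >=31). The gap factor scores
#' *recovery opportunity*, so longer gaps score lower. All boundaries are
#' data, not code: pass a modified copy to recalibrate regionally (tolerance
#' thresholds are plausibly higher in the Eastern and Southern
#' Mediterranean).
#'
#' Each factor is encoded as lower-edge breakpoints: score = the score of
#' the last breakpoint not exceeding the (rounded) value.
#'
#' @return named list of factor tables, class `scoring_thresholds`
#' @export
default_thresholds <- function() {
  structure(list(
    max_sst = list(breaks = c(-Inf, 24, 27, 29, 32), scores = 1:5,
                   integer_valued = FALSE),
    max_duration = list(breaks = c(0, 5, 11, 21, 31), scores = 1:5,
                        integer_valued = TRUE),
    n_events = list(breaks = c(0, 1, 2, 3, 4), scores = 1:5,
                    integer_valued = TRUE),
    gap = list(breaks = c(0, 5, 20, 40, 60), scores = c(5, 4, 3, 2, 1),
               integer_valued = TRUE)
  ), class = "scoring_thresholds")
}

#' Score one susceptibility factor
#'
#' @param value metric value: max SST in degrees C, durations/gaps in days,
#'   or an event count; fractional values of integer-valued factors are
#'   rounded half-up before lookup
#' @param factor one of `"max_sst"`, `"max_duration"`, `"n_events"`, `"gap"`
#' @param thresholds a `scoring_thresholds` table ([default_thresholds()])
#' @return integer score 1-5
#' @examples
#' score_factor(30, "max_sst")    # 4
#' score_factor(0, "n_events")    # 1
#' score_factor(45, "gap")        # 2
#' @export
score_factor <- function(value, factor = c("max_sst", "max_duration",
                                           "n_events", "gap"),
                         thresholds = default_thresholds()) {
  factor <- match.arg(factor)
  tab <- thresholds[[factor]]
  if (!is.finite(value)) stop_mesa("non-finite value for factor ", factor)
  if (factor != "max_sst" && value < 0) {
    stop_mesa("negative ", factor, " (", value, ") is invalid")
  }
  if (tab$integer_valued) value <- round_half_up(value)
  k <- findInterval(value, tab$breaks)
  if (k < 1) k <- 1
  as.integer(tab$scores[k])
}

#' Impact severity of aggregated metrics
#'
#' Equal-weight arithmetic mean of the max-SST and max-duration factor
#' scores; values land on a 1-5 grid in steps of 0.5.
#'
#' @param metrics one metrics row ([season_metrics()] or
#'   [aggregate_metrics()])
#' @param thresholds a `scoring_thresholds` table
#' @return numeric in `[1, 5]`
#' @export
impact_severity <- function(metrics, thresholds = default_thresholds()) {
  (score_factor(metrics$max_sst_c, "max_sst", thresholds) +
     score_factor(metrics$max_run_days, "max_duration", thresholds)) / 2
}

#' Potential for recovery of aggregated metrics
#'
#' Equal-weight arithmetic mean of the event-frequency and inter-event-gap
#' factor scores. High scores mean *low* recovery opportunity (many events,
#' short gaps), i.e. higher susceptibility.
#'
#' @inheritParams impact_severity
#' @return numeric in `[1, 5]`
#' @export
recovery_potential <- function(metrics, thresholds = default_thresholds()) {
  (score_factor(metrics$n_events, "n_events", thresholds) +
     score_factor(metrics$max_gap_days, "gap", thresholds)) / 2
}

#' The MESA susceptibility matrix
#'
#' The 5x5 lookup combining impact severity (columns) with potential for
#' recovery (rows), each 1-5, into a single susceptibility score. The
#' printed table equals `ceiling((is + pr) / 2)` on every cell; it is
#' hard-coded as printed and the closed form is asserted in the test suite.
#'
#' @return 5x5 integer matrix, rows = recovery, columns = impact severity
#' @export
susceptibility_matrix <- function() {
  matrix(as.integer(c(
    1, 2, 2, 3, 3,
    2, 2, 3, 3, 4,
    2, 3, 3, 4, 4,
    3, 3, 4, 4, 5,
    3, 4, 4, 5, 5
  )), nrow = 5, byrow = TRUE,
  dimnames = list(recovery = 1:5, impact_severity = 1:5))
}

#' Combine impact severity and recovery into a susceptibility score
#'
#' Fractional inputs (x.5 from averaging two factor scores) are rounded
#' half-up to integers, then looked up in the susceptibility matrix.
#'
#' @param is_score impact severity in `[1, 5]`
#' @param pr_score potential for recovery in `[1, 5]`
#' @param matrix the combination matrix ([susceptibility_matrix()])
#' @return integer susceptibility score 1-5
#' @examples
#' combine_susceptibility(2, 5)    # 4
#' combine_susceptibility(3.5, 2)  # rounds to (4, 2) -> 3
#' @export
combine_susceptibility <- function(is_score, pr_score,
                                   matrix = susceptibility_matrix()) {
  if (!is.finite(is_score) || !is.finite(pr_score) ||
      is_score < 1 || is_score > 5 || pr_score < 1 || pr_score > 5) {
    stop_mesa("impact severity and recovery scores must lie in [1, 5]")
  }
  matrix[round_half_up(pr_score), round_half_up(is_score)]
}

#' Score a table of aggregated pixel metrics
#'
#' Applies the four factor scorers, averages them into impact severity and
#' potential for recovery, and combines those through the susceptibility
#' matrix — one bundle of scores per pixel.
#'
#' @param metrics data.frame of aggregated metrics rows
#'   ([cube_season_metrics()])
#' @param thresholds a `scoring_thresholds` table
#' @param matrix the combination matrix
#' @return data.frame: `pixel_id`, the four factor scores, `impact_severity`,
#'   `recovery_potential`, `susceptibility`
#' @export
score_pixels <- function(metrics, thresholds = default_thresholds(),
                         matrix = susceptibility_matrix()) {
  rows <- lapply(seq_len(nrow(metrics)), function(k) {
    m <- metrics[k, ]
    sst <- score_factor(m$max_sst_c, "max_sst", thresholds)
    dur <- score_factor(m$max_run_days, "max_duration", thresholds)
    frq <- score_factor(m$n_events, "n_events", thresholds)
    gap <- score_factor(m$max_gap_days, "gap", thresholds)
    is_s <- (sst + dur) / 2
    pr_s <- (frq + gap) / 2
    data.frame(
      pixel_id = m$pixel_id,
      sst_score = sst, duration_score = dur,
      frequency_score = frq, gap_score = gap,
      impact_severity = is_s, recovery_potential = pr_s,
      susceptibility = combine_susceptibility(is_s, pr_s, matrix),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
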