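# Sensitivity = susceptibility x importance, binned into the five MESA
# sensitivity classes.

SENSITIVITY_LEVELS <- c("Very Low", "Low", "Moderate", "High", "Very High")

#' Default sensitivity bins
#'
#' Products of susceptibility (1-5) and importance ({1, 3, 5}) range over
#' 1-25 and are binned into the five sensitivity classes. The reference
#' protocol combines the scores by a multiplication matrix whose exact cell
#' values are not published; these bins are a reconstruction calibrated to
#' the published qualitative pattern (a 3 x 3 product is Moderate; 4 x 5 and
#' above is Very High; susceptibility 3-4 with importance 1 is Low) and are
#' fully configurable.
#'
#' @param boundaries upper product bound of each class, ascending, last = 25
#' @return object of class `sensitivity_bins`
#' @export
sensitivity_bins <- function(boundaries = c(2, 5, 10, 15, 25)) {
  if (length(boundaries) != 5 || is.unsorted(boundaries, strictly = TRUE) ||
      boundaries[5] != 25 || boundaries[1] < 1) {
    stop_mesa("boundaries must be 5 ascending product bounds ending at 25")
  }
  structure(list(boundaries = boundaries, labels = SENSITIVITY_LEVELS),
            class = "sensitivity_bins")
}

#' Combine susceptibility and importance into a sensitivity class
#'
#' @param susceptibility integer 1-5
#' @param importance integer in {1, 3, 5}
#' @param bins a [sensitivity_bins()]
#' @return ordered factor with the five sensitivity levels
#' @examples
#' combine_sensitivity(1, 1)  # Very Low
#' combine_sensitivity(4, 5)  # Very High
#' combine_sensitivity(3, 3)  # Moderate
#' @export
combine_sensitivity <- function(susceptibility, importance,
                                bins = sensitivity_bins()) {
  if (!susceptibility %in% 1:5) {
    stop_mesa("susceptibility must be an integer 1-5, got ", format(susceptibility))
  }
  if (!importance %in% c(1L, 3L, 5L)) {
    stop_mesa("importance must be one of {1, 3, 5}, got ", format(importance))
  }
  product <- susceptibility * importance
  k <- findInterval(product, c(1, bins$boundaries[-5] + 1))
  factor(bins$labels[k], levels = bins$labels, ordered = TRUE)
}

#' Assemble the per-cell sensitivity surface
#'
#' @param susc named vector cell_id -> susceptibility (1-5)
#' @param imp named vector cell_id -> importance ({1, 3, 5}); must cover
#'   exactly the same cells as `susc`
#' @param bins a [sensitivity_bins()]
#' @return data.frame of class `sensitivity_surface`: `cell_id`,
#'   `susceptibility`, `importance`, `product`, `class` (ordered factor)
#' @export
build_sensitivity_surface <- function(susc, imp, bins = sensitivity_bins()) {
  d <- c(setdiff(names(susc), names(imp)), setdiff(names(imp), names(susc)))
  if (length(d) > 0) {
    stop_mesa("susceptibility and importance cell sets differ: ",
              paste(sort(d), collapse = ", "))
  }
  if (length(susc) == 0) {
    out <- data.frame(cell_id = character(0), susceptibility = integer(0),
                      importance = integer(0), product = integer(0),
                      class = factor(character(0), levels = SENSITIVITY_LEVELS,
                                     ordered = TRUE),
                      stringsAsFactors = FALSE)
    class(out) <- c("sensitivity_surface", "data.frame")
    return(out)
  }
  imp <- imp[names(susc)]
  cls <- mapply(function(s, i) as.character(combine_sensitivity(s, i, bins)),
                susc, imp)
  out <- data.frame(
    cell_id = names(susc),
    susceptibility = as.integer(susc),
    importance = as.integer(imp),
    product = as.integer(susc) * as.integer(imp),
    class = factor(cls, levels = SENSITIVITY_LEVELS, ordered = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("sensitivity_surface", "data.frame")
  out
}

#' @export
print.sensitivity_surface <- function(x, ...) {
  cat("sensitivity_surface:", nrow(x), "cells\n")
  print(table(x$class))
  invisible(as.data.frame(x))
}
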