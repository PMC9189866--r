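#' Round half away from zero
#'
#' Categorical class lookups in this package operate on integers; metrics
#' averaged over the study years can be fractional, and the convention here
#' is that halves round up (3.5 -> 4). Base `round()` rounds halves to even,
#' so a dedicated helper is used wherever a fractional score or metric must
#' be mapped onto an integer class.
#'
#' @param x numeric vector
#' @return `x` rounded to the nearest integer, halves away from zero
#' @examples
#' round_half_up(c(2.5, 3.5, 3.4))
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mesa <- function(...) stop(..., call. = FALSE)

warn_mesa <- function(...) warning(..., call. = FALSE)
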