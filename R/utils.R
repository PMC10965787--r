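# internal helpers shared across modules

clamp <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

#' Round half-up
#'
#' `round()` uses banker's rounding; displayed table percentages use
#' conventional half-up rounding instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count as "N (p%)" with half-up rounding to one decimal
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @return Character scalar, e.g. `"315 (68.5%)"`.
#' @export
fmt_count_pct <- function(count, total) {
  sprintf("%d (%.1f%%)", count, round_half_up(100 * count / total, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)
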