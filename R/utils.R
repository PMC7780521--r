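#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero
#' (e.g. 0.25 -> 0.3 at one decimal), the convention used throughout the
#' package's printed percentage tables. Base `round()` rounds half to
#' even, which disagrees on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an epsilon scaled to x to defeat binary misrepresentation
  # of decimal halves before taking the floor
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a denominator, printed-table convention
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s), rounded half away from zero.
#' @export
pct <- function(num, den, digits = 1) {
  round_half_away(100 * num / den, digits)
}

age_days <- function(date, birth_date) {
  as.integer(as.Date(date) - as.Date(birth_date))
}
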