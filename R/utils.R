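#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero (1.125 ->
#' 1.13 at 2 digits), the convention of printed codon-usage tables; base
#' `round()` rounds halves to even. Implemented with a tiny relative nudge
#' so binary representation of decimals does not flip ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded.
#' @examples
#' round_half_up(1.125, 2) # 1.13
#' round(1.125, 2)         # 1.12
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# fixed-width numeric formatting for TSV reports (half-up, trailing zeros)
format_fixed <- function(x, digits) {
  out <- formatC(round_half_up(x, digits), format = "f", digits = digits)
  out[is.na(x)] <- "NA"
  out
}
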