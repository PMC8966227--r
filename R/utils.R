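#' Round half away from zero
#'
#' Commercial ("round half up") rounding, as used when tabulating ECG ratios:
#' ties at 5 in the first dropped digit round away from zero, unlike base R's
#' [round()], which rounds half to even. The published QRS/QTc columns are
#' reproduced from the printed QRS and QTc values only under this convention
#' (e.g. 85/515 = 0.16504... reports as 0.17).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded to `digits` decimal places.
#' @examples
#' round_half_up(0.165, 2) # 0.17, where round(0.165, 2) gives 0.16
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small relative nudge counters binary representation of decimal ties
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# shared stop helper: consistent error classes for validation failures
qrsqtc_abort <- function(msg, class) {
  abort(msg, class = c(class, "qrsqtc_error"))
}
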