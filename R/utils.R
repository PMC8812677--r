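#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all displayed rates and shares,
#' matching the usual presentation convention for registry tables (base R's
#' [round()] rounds half to even).  Values within 1e-9 of a half boundary
#' are treated as lying on it, which protects decimal fractions such as
#' 97/200 from binary-representation jitter.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(0.485)  # 0.49
#' round(0.485, 2)       # 0.48 (half to even)
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' First days of the calendar months covering a date interval
#' @noRd
month_seq <- function(from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  seq(as.Date(format(from, "%Y-%m-01")), as.Date(format(to, "%Y-%m-01")),
      by = "month")
}

#' Number of days in the month starting at `month_start`
#' @noRd
days_in_month <- function(month_start) {
  as.integer(seq(as.Date(month_start), by = "month", length.out = 2)[2] -
               as.Date(month_start))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a stage-prefixed message (used by the pipeline driver)
#' @noRd
stage_stop <- function(stage, e) {
  stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
}
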