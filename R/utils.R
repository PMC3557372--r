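#' Round half away from zero
#'
#' Decimal rounding in which exact halves round up (away from zero), the
#' convention used for printed percentage tables. Base [round()] uses
#' round-half-to-even, which disagrees on values such as 0.05.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(2.05, 2.15, 2.25), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so that values which are exact halves in
  # decimal but sit just below .5 in binary still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# shared input check: a data frame with required columns
check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "tickniche_schema_error")
  }
  invisible(data)
}
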