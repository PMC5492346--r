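#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), matching how the source
#' cohort percentages are printed (e.g. 22/47 -> 46.8). Base `round()` uses
#' round-half-to-even, which differs on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up, same length as `x`.
#' @examples
#' round_half_up(0.25, 1)   # 0.3, where round(0.25, 1) gives 0.2
#' round_half_up(100 * 22 / 47, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # tiny relative nudge so values that are exact ties in decimal but sit just
  # under .5 in binary (e.g. 0.145 * 10 = 1.4499999...) still round up
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

pct <- function(count, n, digits = 1) {
  round_half_up(100 * count / n, digits)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "heatstrain_schema_error")
  }
  invisible(df)
}
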