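#' Natural wet-bulb temperature from air temperature and humidity
#'
#' Closed-form psychrometric approximation of the natural wet-bulb
#' temperature Tw (degrees C) from dry-bulb temperature and relative
#' humidity:
#'
#' \deqn{T_w = T_a \arctan(0.151977 \sqrt{RH + 8.313659})
#'   + \arctan(T_a + RH) - \arctan(RH - 1.676331)
#'   + 0.00391838\, RH^{3/2} \arctan(0.023101\, RH) - 4.686035}
#'
#' All arctangents operate in radians. The `Ta + RH` term mixes units as the
#' formula is published; it is implemented literally, not "corrected". The
#' fit was calibrated for roughly RH in \[5, 99\] % and Ta in \[-20, 50\]
#' degrees C (see [wbgt_valid()]); the value is still computed outside that
#' envelope, never clamped.
#'
#' @param ta Dry-bulb air temperature, degrees C. Vectorized.
#' @param rh Relative humidity, percent (>= 0). Vectorized.
#' @return Estimated wet-bulb temperature in degrees C.
#' @examples
#' stull_wet_bulb(20, 50) # about 13.70
#' @export
stull_wet_bulb <- function(ta, rh) {
  check_meteo_inputs(ta, rh)
  ta * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(ta + rh) -
    atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) -
    4.686035
}

check_meteo_inputs <- function(ta, rh) {
  if (length(ta) != length(rh)) {
    if (length(ta) != 1L && length(rh) != 1L) {
      abort("ta and rh must have equal length (or one be scalar)",
            class = "heatstrain_domain_error")
    }
  }
  if (any(!is.finite(ta)) || any(!is.finite(rh))) {
    abort("ta and rh must be finite", class = "heatstrain_domain_error")
  }
  if (any(rh < 0)) {
    abort("rh must be >= 0 %", class = "heatstrain_domain_error")
  }
  invisible(NULL)
}

#' Validity envelope of the WBGT estimation formulas
#'
#' TRUE where the inputs fall inside the envelope the wet-bulb fit was
#' calibrated for: RH in \[5, 99\] % and Ta in \[-20, 50\] degrees C.
#' Estimates outside it are still computed but should be flagged, so daily
#' aggregation can exclude them without silently dropping hours.
#'
#' @inheritParams stull_wet_bulb
#' @return Logical vector.
#' @export
wbgt_valid <- function(ta, rh) {
  rh >= 5 & rh <= 99 & ta >= -20 & ta <= 50
}

#' Estimate WBGT from air temperature and relative humidity
#'
#' Two-step regression estimate of outdoor wet-bulb globe temperature:
#' Tw from [stull_wet_bulb()], then
#' \deqn{WBGT = -0.24418 + 0.553991\,T_w + 0.455346\,T_a
#'   - 0.00217\,T_w^2 + 0.002782\,T_w T_a}
#' No globe-temperature, solar or wind input is used; the estimate stands in
#' for measured WBGT where only standard station variables exist.
#'
#' @inheritParams stull_wet_bulb
#' @return A tibble with one row per input: `tw`, `wbgt` (degrees C) and
#'   `valid` (inside the calibration envelope, see [wbgt_valid()]).
#' @examples
#' park_wbgt(30, 70)
#' @export
park_wbgt <- function(ta, rh) {
  tw <- stull_wet_bulb(ta, rh)
  wbgt <- -0.24418 + 0.553991 * tw + 0.455346 * ta -
    0.00217 * tw^2 + 0.002782 * tw * ta
  tibble::tibble(tw = tw, wbgt = wbgt, valid = wbgt_valid(ta, rh))
}

#' Estimate WBGT for every observation in a series
#'
#' @param series A `meteo_series` (see [meteo_series()]).
#' @return The series with `tw`, `wbgt` and `valid` columns appended; row
#'   order and length are preserved.
#' @export
series_wbgt <- function(series) {
  series <- validate_meteo_series(series)
  est <- park_wbgt(series$ta, series$rh)
  series$tw <- est$tw
  series$wbgt <- est$wbgt
  series$valid <- est$valid
  series
}
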