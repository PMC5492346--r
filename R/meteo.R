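#' Construct an hourly meteorological series
#'
#' A `meteo_series` is a tibble with one row per observation from a single
#' station: `station_id`, `timestamp` (local civil time, minute resolution),
#' `ta` (dry-bulb air temperature, degrees C) and `rh` (relative humidity, %).
#' Timestamps are stored as POSIXct in a fixed "UTC" representation standing
#' in for naive local time: station exports carry no offset and the analysis
#' never crosses time zones.
#'
#' @param timestamp POSIXct (or coercible) vector of observation times,
#'   strictly increasing.
#' @param ta Dry-bulb air temperature in degrees C, within \[-50, 60\].
#' @param rh Relative humidity in percent, within \[0, 100\].
#' @param station_id Single opaque station identifier.
#' @return A tibble of class `meteo_series`.
#' @examples
#' meteo_series(
#'   timestamp = as.POSIXct("2013-08-01 00:00", tz = "UTC") + 3600 * 0:23,
#'   ta = 25 + 5 * sin(2 * pi * (0:23 - 9) / 24),
#'   rh = rep(60, 24)
#' )
#' @export
meteo_series <- function(timestamp, ta, rh, station_id = "station") {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  out <- tibble::tibble(
    station_id = as.character(station_id),
    timestamp = timestamp,
    ta = as.numeric(ta),
    rh = as.numeric(rh)
  )
  validate_meteo_series(out)
}

#' Validate a meteorological series
#'
#' Checks the `meteo_series` invariants on any data frame with the right
#' columns: non-empty, strictly increasing timestamps with no duplicates,
#' `ta` within \[-50, 60\] degrees C and `rh` within \[0, 100\] %.
#'
#' @param x Data frame with columns `station_id`, `timestamp`, `ta`, `rh`.
#' @return `x` as a tibble of class `meteo_series`, invisibly usable onward.
#' @export
validate_meteo_series <- function(x) {
  assert_columns(x, c("station_id", "timestamp", "ta", "rh"), "meteo series")
  if (nrow(x) == 0) {
    abort("meteo series is empty", class = "heatstrain_empty_input")
  }
  if (anyNA(x$timestamp)) {
    abort("meteo series has missing timestamps", class = "heatstrain_schema_error")
  }
  dt <- diff(as.numeric(x$timestamp))
  if (any(dt <= 0)) {
    abort(
      "meteo series timestamps must be strictly increasing (no duplicates)",
      class = "heatstrain_order_error"
    )
  }
  bad_ta <- which(!is.na(x$ta) & (x$ta < -50 | x$ta > 60))
  bad_rh <- which(!is.na(x$rh) & (x$rh < 0 | x$rh > 100))
  if (length(bad_ta) > 0) {
    abort(sprintf("ta outside [-50, 60] degC at row(s) %s",
                  paste(head(bad_ta, 5), collapse = ", ")),
          class = "heatstrain_domain_error")
  }
  if (length(bad_rh) > 0) {
    abort(sprintf("rh outside [0, 100] %% at row(s) %s",
                  paste(head(bad_rh, 5), collapse = ", ")),
          class = "heatstrain_domain_error")
  }
  out <- tibble::as_tibble(x)
  class(out) <- unique(c("meteo_series", class(out)))
  out
}

#' Read an hourly weather CSV
#'
#' Expects the station-export layout `station_id, timestamp, ta_c, rh_pct`
#' with a mandatory header; timestamps are ISO 8601 local time without an
#' offset.
#'
#' @param path Path to the CSV file.
#' @return A validated `meteo_series` tibble.
#' @seealso [write_weather()]
#' @export
read_weather <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      station_id = readr::col_character(),
      timestamp = readr::col_datetime(format = ""),
      ta_c = readr::col_double(),
      rh_pct = readr::col_double()
    )
  )
  assert_columns(df, c("station_id", "timestamp", "ta_c", "rh_pct"),
                 sprintf("weather file '%s'", path))
  meteo_series(
    timestamp = df$timestamp, ta = df$ta_c, rh = df$rh_pct,
    station_id = if (nrow(df)) df$station_id else "station"
  )
}

#' Write an hourly weather CSV
#'
#' Inverse of [read_weather()]; any estimate columns already present
#' (`tw`, `wbgt`, `valid`) are appended as `tw_c`, `wbgt_c`, `valid`.
#'
#' @param series A `meteo_series` (optionally with WBGT estimate columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path) {
  out <- tibble::tibble(
    station_id = series$station_id,
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
    ta_c = series$ta,
    rh_pct = series$rh
  )
  if (all(c("tw", "wbgt", "valid") %in% names(series))) {
    out$tw_c <- series$tw
    out$wbgt_c <- series$wbgt
    out$valid <- as.integer(series$valid)
  }
  readr::write_csv(out, path)
  invisible(path)
}
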