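# Independent scalar re-codings of the two published formulas, kept separate
# from the package implementation so equivalence checks exercise two paths.
# Each is a direct term-by-term transcription evaluated with a loop.

oracle_wet_bulb <- function(ta, rh) {
  stopifnot(length(ta) == length(rh))
  out <- numeric(length(ta))
  for (i in seq_along(ta)) {
    t1 <- ta[i] * atan(0.151977 * (rh[i] + 8.313659)^(1 / 2))
    t2 <- atan(ta[i] + rh[i])
    t3 <- atan(rh[i] - 1.676331)
    t4 <- 0.00391838 * (rh[i])^(3 / 2) * atan(0.023101 * rh[i])
    out[i] <- t1 + t2 - t3 + t4 - 4.686035
  }
  out
}

oracle_wbgt <- function(ta, rh) {
  out <- numeric(length(ta))
  for (i in seq_along(ta)) {
    tw <- oracle_wet_bulb(ta[i], rh[i])
    out[i] <- -0.24418 + 0.553991 * tw + 0.455346 * ta[i] -
      0.00217 * tw^2 + 0.002782 * tw * ta[i]
  }
  out
}

# Brute-force run scanner: marks each day TRUE iff it sits in a run of
# >= min_run consecutive calendar days with tmax >= threshold. O(n^2) by
# design — checks every candidate window directly.
oracle_episode_days <- function(dates, tmax, threshold = 33, min_run = 2L) {
  n <- length(dates)
  member <- rep(FALSE, n)
  d <- as.integer(dates)
  for (i in seq_len(n)) {
    for (j in i:n) {
      window <- i:j
      consecutive <- all(diff(d[window]) == 1L)
      if (!consecutive) break
      all_hot <- all(!is.na(tmax[window]) & tmax[window] >= threshold)
      if (all_hot && length(window) >= min_run) {
        member[window] <- TRUE
      }
    }
  }
  member
}

# a full hourly day-sequence series with constant values
constant_series <- function(n_days = 3, ta = 30, rh = 60,
                            start = "2013-08-01") {
  n <- n_days * 24
  meteo_series(
    timestamp = as.POSIXct(paste(start, "00:00:00"), tz = "UTC") +
      3600 * (seq_len(n) - 1),
    ta = rep(ta, n), rh = rep(rh, n)
  )
}

# daily summaries whose dates/tmax are given directly
daily_from_tmax <- function(tmax, start = as.Date("2013-08-01"),
                            dates = start + seq_along(tmax) - 1) {
  tibble::tibble(date = dates, tmax = tmax, night_tmin = NA_real_,
                 wbgt_max = NA_real_)
}
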