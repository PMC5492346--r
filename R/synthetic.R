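#' Configuration for the synthetic hourly weather generator
#'
#' Describes a summer urban weather scenario: a sinusoid-like diurnal cycle
#' (minimum near 06:00, maximum near 15:00) around a base mean, declared
#' heat-wave episodes that lift daytime maxima to a chosen peak, declared
#' tropical nights whose window minima are held strictly above 25 degrees C,
#' relative humidity anti-phased with temperature, and optional Gaussian
#' noise.
#'
#' @param n_days Number of simulated days.
#' @param base_tmean Base daily mean temperature, degrees C.
#' @param diurnal_amplitude Half-range of the diurnal cycle, degrees C (the
#'   noiseless daily maximum is `base_tmean + diurnal_amplitude`).
#' @param heatwave_episodes List of episodes, each
#'   `list(start_day =, length =, peak_tmax =)` with `length >= 2` and
#'   `peak_tmax >= 33` (1-based day indices).
#' @param tropical_nights Integer day indices d whose preceding night
#'   (evening of day d-1 through morning of day d) is made tropical.
#' @param night_floor_c Temperature floor applied over declared tropical
#'   nights, degrees C (must exceed 25).
#' @param rh_base Mean relative humidity, %.
#' @param rh_diurnal_amplitude Humidity swing anti-phased with the diurnal
#'   temperature anomaly, percentage points.
#' @param noise_sd Standard deviation of additive Gaussian temperature
#'   noise, degrees C.
#' @param start_date First simulated calendar day.
#' @param station_id Station label written on the series.
#' @param seed Integer seed; identical configs give identical series.
#' @return A validated `weather_gen_config` list.
#' @export
weather_gen_config <- function(n_days = 30L,
                               base_tmean = 25,
                               diurnal_amplitude = 5,
                               heatwave_episodes = list(),
                               tropical_nights = integer(),
                               night_floor_c = 26,
                               rh_base = 65,
                               rh_diurnal_amplitude = 20,
                               noise_sd = 0.5,
                               start_date = as.Date("2013-07-01"),
                               station_id = "SYN-001",
                               seed = 1L) {
  cfg <- list(
    n_days = as.integer(n_days), base_tmean = base_tmean,
    diurnal_amplitude = diurnal_amplitude,
    heatwave_episodes = heatwave_episodes,
    tropical_nights = as.integer(tropical_nights),
    night_floor_c = night_floor_c,
    rh_base = rh_base, rh_diurnal_amplitude = rh_diurnal_amplitude,
    noise_sd = noise_sd, start_date = as.Date(start_date),
    station_id = station_id, seed = as.integer(seed)
  )
  if (cfg$n_days < 1) {
    abort("n_days must be >= 1", class = "heatstrain_config_error")
  }
  for (ep in cfg$heatwave_episodes) {
    if (!all(c("start_day", "length", "peak_tmax") %in% names(ep))) {
      abort("each episode needs start_day, length, peak_tmax",
            class = "heatstrain_config_error")
    }
    if (ep$length < 2) {
      abort("episode length must be >= 2 days", class = "heatstrain_config_error")
    }
    if (ep$peak_tmax < 33) {
      abort("episode peak_tmax must be >= 33 degC",
            class = "heatstrain_config_error")
    }
    if (ep$start_day < 1 || ep$start_day + ep$length - 1 > cfg$n_days) {
      abort("episode extends outside the simulated period",
            class = "heatstrain_config_error")
    }
  }
  if (any(cfg$tropical_nights < 2L | cfg$tropical_nights > cfg$n_days)) {
    # d = 1 has no preceding simulated evening, so its night is indeterminate
    abort("tropical_nights indices must lie in [2, n_days]",
          class = "heatstrain_config_error")
  }
  if (cfg$night_floor_c <= 25) {
    abort("night_floor_c must exceed the 25 degC tropical-night threshold",
          class = "heatstrain_config_error")
  }
  if (cfg$rh_base - cfg$rh_diurnal_amplitude < 5 ||
      cfg$rh_base + cfg$rh_diurnal_amplitude > 99) {
    abort("rh_base +/- rh_diurnal_amplitude must stay within [5, 99] %",
          class = "heatstrain_config_error")
  }
  if (cfg$noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "heatstrain_config_error")
  }
  structure(cfg, class = "weather_gen_config")
}

# normalized diurnal anomaly in [-1, 1]: -1 at 06:00, +1 at 15:00, built from
# two half-cosine arcs (9 h warming, 15 h cooling) so both turning points sit
# where observed urban summer series put them
diurnal_anomaly <- function(hour) {
  h <- hour %% 24
  ifelse(
    h >= 6 & h <= 15,
    -cos(pi * (h - 6) / 9),
    cos(pi * ((h - 15) %% 24) / 15)
  )
}

#' Generate a synthetic hourly weather series
#'
#' Temperature is `base_tmean + diurnal_amplitude * a(h) + noise`, where
#' `a(h)` is the normalized diurnal anomaly (-1 at 06:00, +1 at 15:00).
#' Declared heat-wave episodes add `(peak_tmax - base - amplitude)` scaled
#' by the positive part of `a(h)`, lifting afternoons to the declared peak
#' while leaving nights untouched (so episodes do not create undeclared
#' tropical nights). Declared tropical nights clamp the night window (18:00
#' previous evening to 09:00) from below at `night_floor_c`. Humidity is
#' `rh_base - rh_diurnal_amplitude * a(h)`, clipped to \[5, 99\] — a simple
#' anti-correlation, not a moisture model.
#'
#' @param config A [weather_gen_config()].
#' @return A `meteo_series` with `n_days * 24` hourly rows; identical
#'   configs (including `seed`) give identical output. The seed is recorded
#'   in the `"gen_seed"` attribute.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "weather_gen_config"))
  n_hours <- config$n_days * 24L
  timestamp <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC") +
    3600 * (seq_len(n_hours) - 1L)
  hour <- (seq_len(n_hours) - 1L) %% 24L
  day <- (seq_len(n_hours) - 1L) %/% 24L + 1L # 1-based day index
  a <- diurnal_anomaly(hour)

  ta <- config$base_tmean + config$diurnal_amplitude * a
  for (ep in config$heatwave_episodes) {
    days <- seq(ep$start_day, ep$start_day + ep$length - 1L)
    lift <- ep$peak_tmax - (config$base_tmean + config$diurnal_amplitude)
    sel <- day %in% days
    ta[sel] <- ta[sel] + lift * pmax(a[sel], 0)
  }
  if (config$noise_sd > 0) {
    ta <- ta + withr::with_seed(config$seed,
                                rnorm(n_hours, sd = config$noise_sd))
  }
  # hold declared tropical nights above the threshold (window ending on the
  # morning of the declared day), after noise so the guarantee is exact
  for (d in config$tropical_nights) {
    in_night <- (day == d - 1L & hour >= 18L) | (day == d & hour <= 9L)
    ta[in_night] <- pmax(ta[in_night], config$night_floor_c)
  }
  rh <- pmin(99, pmax(5, config$rh_base - config$rh_diurnal_amplitude * a))
  out <- meteo_series(timestamp, ta, rh, station_id = config$station_id)
  attr(out, "gen_seed") <- config$seed
  out
}

#' Configuration for the synthetic worker-cohort generator
#'
#' Marginal structure mirroring the published 47-case cohort: independent
#' Bernoulli exposure/personal flags, uniform ages, and a truncated-Gaussian
#' maximum WBGT. Defaults are the cohort's observed prevalences and WBGT
#' moments (n = 47; heavy 41/47, unacclimatized 22/47, heat wave 29/47,
#' tropical night 37/47; WBGT mean 29.9, sd 2.0, ages 29-77).
#'
#' @param n_cases Cohort size (>= 1).
#' @param p_heavy,p_unacclimatized,p_heat_wave,p_tropical_night Flag
#'   prevalences in \[0, 1\].
#' @param wbgt_mean,wbgt_sd Moments of the WBGT distribution before
#'   truncation to \[18, 38\] degrees C.
#' @param age_range Two-element integer range of ages (inclusive).
#' @param seed Integer seed.
#' @return A validated `cohort_gen_config` list.
#' @export
cohort_gen_config <- function(n_cases = 47L,
                              p_heavy = 41 / 47,
                              p_unacclimatized = 22 / 47,
                              p_heat_wave = 29 / 47,
                              p_tropical_night = 37 / 47,
                              wbgt_mean = 29.9,
                              wbgt_sd = 2.0,
                              age_range = c(29L, 77L),
                              seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), p_heavy = p_heavy,
    p_unacclimatized = p_unacclimatized, p_heat_wave = p_heat_wave,
    p_tropical_night = p_tropical_night,
    wbgt_mean = wbgt_mean, wbgt_sd = wbgt_sd,
    age_range = as.integer(age_range), seed = as.integer(seed)
  )
  probs <- c(cfg$p_heavy, cfg$p_unacclimatized, cfg$p_heat_wave,
             cfg$p_tropical_night)
  if (any(probs < 0 | probs > 1)) {
    abort("prevalences must lie in [0, 1]", class = "heatstrain_config_error")
  }
  if (cfg$n_cases < 1) {
    abort("n_cases must be >= 1", class = "heatstrain_config_error")
  }
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) < 0 ||
      cfg$age_range[1] < 15 || cfg$age_range[2] > 100) {
    abort("age_range must be an increasing pair within [15, 100]",
          class = "heatstrain_config_error")
  }
  if (cfg$wbgt_sd <= 0) {
    abort("wbgt_sd must be positive", class = "heatstrain_config_error")
  }
  structure(cfg, class = "cohort_gen_config")
}

#' Generate a synthetic worker cohort
#'
#' @param config A [cohort_gen_config()].
#' @return A worker-case tibble with `n_cases` rows (onset dates left NA —
#'   flags are drawn directly, not derived from weather). The seed is
#'   recorded in the `"gen_seed"` attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_gen_config"))
  n <- config$n_cases
  withr::with_seed(config$seed, {
    wbgt <- rnorm(n, config$wbgt_mean, config$wbgt_sd)
    # resample outliers until every draw lies in the plausible [18, 38] band
    out_of_band <- which(wbgt < 18 | wbgt > 38)
    while (length(out_of_band) > 0) {
      wbgt[out_of_band] <- rnorm(length(out_of_band),
                                 config$wbgt_mean, config$wbgt_sd)
      out_of_band <- which(wbgt < 18 | wbgt > 38)
    }
    cohort <- tibble::tibble(
      case_id = sprintf("S%04d", seq_len(n)),
      age = sample(seq(config$age_range[1], config$age_range[2]), n,
                   replace = TRUE),
      heavy_exertion = rbinom(n, 1, config$p_heavy) == 1,
      unacclimatized = rbinom(n, 1, config$p_unacclimatized) == 1,
      onset_date = as.Date(NA),
      tropical_night = rbinom(n, 1, config$p_tropical_night) == 1,
      heat_wave = rbinom(n, 1, config$p_heat_wave) == 1,
      wbgt_max = wbgt
    )
  })
  attr(cohort, "gen_seed") <- config$seed
  cohort
}
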