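test_that("weather generation is seed-deterministic", {
  cfg <- weather_gen_config(n_days = 5, seed = 99)
  w1 <- generate_weather(cfg)
  w2 <- generate_weather(cfg)
  expect_equal(w1, w2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_weather(w1, p1)
  write_weather(w2, p2)
  expect_identical(readLines(p1), readLines(p2))
  w3 <- generate_weather(weather_gen_config(n_days = 5, seed = 100))
  expect_false(isTRUE(all.equal(w1$ta, w3$ta)))
})

test_that("noiseless diurnal curve hits its closed-form extremes", {
  cfg <- weather_gen_config(n_days = 4, base_tmean = 25,
                            diurnal_amplitude = 5, noise_sd = 0)
  d <- daily_summaries(generate_weather(cfg))
  expect_equal(d$tmax, rep(30, 4))
  expect_equal(d$night_tmin[-1], rep(20, 3))
  expect_identical(nrow(detect_heat_waves(d)), 0L)
})

test_that("declared episodes and nights come out of the full chain exactly", {
  cfg <- weather_gen_config(
    n_days = 12,
    heatwave_episodes = list(
      list(start_day = 4, length = 3, peak_tmax = 35.5),
      list(start_day = 9, length = 2, peak_tmax = 33.0)
    ),
    tropical_nights = c(3, 5, 9),
    noise_sd = 0
  )
  w <- generate_weather(cfg)
  d <- daily_summaries(w)
  ep <- detect_heat_waves(d)
  expect_equal(ep$start_date, cfg$start_date + c(3, 8))
  expect_equal(ep$end_date, cfg$start_date + c(5, 9))
  expect_equal(ep$peak_tmax, c(35.5, 33.0))
  # tropical-night flags (days 2..12; day 1 indeterminate by construction)
  flags <- is_tropical_night(d$night_tmin)
  expect_true(is.na(flags[1]))
  expect_identical(which(flags[-1]) + 1L, c(3L, 5L, 9L))

  # the same declarations survive per-case flag derivation
  onsets <- tibble::tibble(
    case_id = as.character(4:12), age = 40, heavy_exertion = TRUE,
    unacclimatized = FALSE, onset_date = cfg$start_date + 3:11,
    tropical_night = NA, heat_wave = NA, wbgt_max = NA_real_
  )
  derived <- derive_flags(onsets, w)
  expect_identical(derived$heat_wave,
                   derived$onset_date %in% (cfg$start_date + c(3:5, 8:9)))
  expect_identical(derived$tropical_night,
                   derived$onset_date %in% (cfg$start_date + c(4, 8)))
})

test_that("generator configs reject invalid declarations", {
  expect_error(weather_gen_config(heatwave_episodes = list(
    list(start_day = 2, length = 1, peak_tmax = 35))),
    class = "heatstrain_config_error")
  expect_error(weather_gen_config(heatwave_episodes = list(
    list(start_day = 2, length = 2, peak_tmax = 30))),
    class = "heatstrain_config_error")
  expect_error(weather_gen_config(tropical_nights = 1),
               class = "heatstrain_config_error")
  expect_error(weather_gen_config(rh_base = 90, rh_diurnal_amplitude = 20),
               class = "heatstrain_config_error")
  expect_error(cohort_gen_config(p_heavy = 1.2),
               class = "heatstrain_config_error")
  expect_error(cohort_gen_config(n_cases = 0),
               class = "heatstrain_config_error")
})

test_that("cohort generation honours degenerate and extreme prevalences", {
  all_on <- generate_cohort(cohort_gen_config(
    n_cases = 25, p_heavy = 1, p_unacclimatized = 1, p_heat_wave = 1,
    p_tropical_night = 1, seed = 5
  ))
  expect_true(all(all_on$heavy_exertion) && all(all_on$unacclimatized) &&
                all(all_on$heat_wave) && all(all_on$tropical_night))
  expect_true(all(all_on$wbgt_max >= 18 & all_on$wbgt_max <= 38))
  expect_true(all(all_on$age >= 29 & all_on$age <= 77))
  expect_equal(generate_cohort(cohort_gen_config(n_cases = 25, seed = 5)),
               generate_cohort(cohort_gen_config(n_cases = 25, seed = 5)))
})

test_that("configured prevalences are recovered at large n", {
  cfg <- cohort_gen_config(n_cases = 1000, seed = 31)
  s <- summarize_cohort(generate_cohort(cfg))
  got <- function(m) s$factors$pct[s$factors$measure == m]
  # 95% binomial margin at n = 1000 is about 3.2 points at p ~ 0.5
  expect_lt(abs(got("unacclimatized") - 100 * cfg$p_unacclimatized), 3.2)
  expect_lt(abs(got("heavy_exertion") - 100 * cfg$p_heavy), 3.2)
  expect_lt(abs(got("heat_wave") - 100 * cfg$p_heat_wave), 3.2)
  expect_lt(abs(got("tropical_night") - 100 * cfg$p_tropical_night), 3.2)
})

test_that("small-cohort counts stay inside their binomial interval", {
  # published-scale cohort: n = 47 at the heat-wave prevalence
  counts <- vapply(1:10, function(seed) {
    ch <- generate_cohort(cohort_gen_config(n_cases = 47, seed = seed))
    sum(ch$heat_wave)
  }, 1L)
  lo <- qbinom(0.025, 47, 29 / 47)
  hi <- qbinom(0.975, 47, 29 / 47)
  expect_true(mean(counts >= lo & counts <= hi) >= 0.8)
})
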