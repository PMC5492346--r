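test_that("the packaged case table loads 47 cases with the printed row values", {
  cases <- heat_cases()
  expect_identical(nrow(cases), 47L)
  r1 <- cases[1, ]
  expect_true(r1$heavy_exertion)
  expect_false(r1$unacclimatized)
  expect_equal(r1$age, 41)
  expect_false(r1$tropical_night)
  expect_true(r1$heat_wave)
  expect_equal(r1$wbgt_max, 31.75)
  # frozen marginal counts from the printed table
  expect_identical(sum(cases$heavy_exertion), 41L)
  expect_identical(sum(cases$unacclimatized), 22L)
  expect_identical(sum(cases$tropical_night), 37L)
  expect_identical(sum(cases$heat_wave), 29L)
})

test_that("case CSV IO round-trips, accepts o/x marks, and names bad rows", {
  cases <- heat_cases()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cases(cases, path)
  expect_equal(read_cases(path), cases)

  # o/x marks parse like booleans
  ox <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "case_id,age,heavy_exertion,unacclimatized,onset_date,tropical_night,heat_wave,wbgt_max",
    "1,41,o,x,2013-08-08,x,o,31.75",
    "2,55,1,0,,,o,32.59"
  ), ox)
  parsed <- read_cases(ox)
  expect_true(parsed$heavy_exertion[1])
  expect_false(parsed$unacclimatized[1])
  expect_true(is.na(parsed$tropical_night[2])) # empty flag = indeterminate
  expect_equal(parsed$onset_date[1], as.Date("2013-08-08"))

  # empty file with header gives an empty typed table
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("case_id,age,heavy_exertion,unacclimatized,onset_date,",
                   "tropical_night,heat_wave,wbgt_max", sep = ""), empty)
  expect_identical(nrow(read_cases(empty)), 0L)

  # schema errors point at the offending row
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "case_id,age,heavy_exertion,unacclimatized,onset_date,tropical_night,heat_wave,wbgt_max",
    "1,forty,1,0,,0,1,31.75"
  ), bad)
  expect_error(read_cases(bad), "row 1", class = "heatstrain_schema_error")
  missing_col <- withr::local_tempfile(fileext = ".csv")
  writeLines("case_id,age", missing_col)
  expect_error(read_cases(missing_col), class = "heatstrain_schema_error")
})

test_that("classification reproduces the published per-case outcomes", {
  cases <- heat_cases()
  cls <- classify_cases(cases)
  expect_identical(sum(cls$exceeds), 45L)
  expect_identical(cls$case_id[!cls$exceeds], c("39", "40"))
  expect_false(cls$exceeds[cls$case_id == "40"]) # heavy, acclimatized, 23.43
  r42 <- cls[cls$case_id == "42", ]
  expect_identical(r42$mclass, "moderate") # not heavy
  expect_true(r42$exceeds) # 32.59 vs 28
  # anything at 50 degC exceeds every configured limit
  hot <- cases[1, ]
  hot$wbgt_max <- 50
  expect_true(classify_cases(hot)$exceeds)
  # incomplete case is an error
  na_case <- cases[1, ]
  na_case$wbgt_max <- NA_real_
  expect_error(classify_cases(na_case), class = "heatstrain_incomplete_case")
})

test_that("cohort summary reproduces the printed proportions", {
  cases <- heat_cases()
  s <- summarize_cohort(cases, classify_cases(cases))
  f <- function(m, col) s$factors[[col]][s$factors$measure == m]
  expect_equal(f("heat_wave", "pct"), 61.7)
  expect_equal(f("tropical_night", "pct"), 78.7)
  expect_equal(f("unacclimatized", "pct"), 46.8)
  expect_equal(f("heavy_exertion", "pct"), 87.2)
  expect_equal(f("exceeds_limit", "pct"), 95.7)
  # decade counts as computed from the printed row-level table
  expect_identical(s$age_decades$count, c(2L, 4L, 14L, 16L, 9L, 2L))
  expect_identical(sum(s$age_decades$count), s$n_total)
})

test_that("summary is permutation-invariant and handles edge cohorts", {
  cases <- heat_cases()
  perm <- sample(nrow(cases))
  s1 <- summarize_cohort(cases)
  s2 <- summarize_cohort(cases[perm, ])
  expect_equal(s1$factors, s2$factors)
  expect_equal(s1$age_decades, s2$age_decades)

  one <- tibble::tibble(
    case_id = "z", age = 44, heavy_exertion = TRUE, unacclimatized = TRUE,
    onset_date = as.Date(NA), tropical_night = TRUE, heat_wave = TRUE,
    wbgt_max = 30
  )
  s_one <- summarize_cohort(one, classify_cases(one))
  expect_true(all(s_one$factors$pct == 100.0))

  # indeterminate flags count as absent but are reported
  ind <- dplyr::bind_rows(one, one)
  ind$tropical_night[2] <- NA
  s_ind <- summarize_cohort(ind)
  tn <- s_ind$factors[s_ind$factors$measure == "tropical_night", ]
  expect_identical(tn$count, 1L)
  expect_identical(tn$n_indeterminate, 1L)

  expect_error(summarize_cohort(heat_cases()[0, ]),
               class = "heatstrain_empty_input")
})

test_that("percentages round half-up to one decimal as printed", {
  expect_equal(round_half_up(100 * 22 / 47, 1), 46.8)
  expect_equal(round_half_up(100 * 45 / 47, 1), 95.7)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(1.45, 1), 1.5) # binary-representation tie
})

test_that("flags derive from weather by the published rules", {
  cfg <- weather_gen_config(
    n_days = 8,
    heatwave_episodes = list(list(start_day = 4, length = 2, peak_tmax = 35)),
    tropical_nights = 5, noise_sd = 0
  )
  w <- generate_weather(cfg)
  onset <- function(day) tibble::tibble(
    case_id = "c", age = 40, heavy_exertion = TRUE, unacclimatized = FALSE,
    onset_date = cfg$start_date + day - 1, tropical_night = NA,
    heat_wave = NA, wbgt_max = NA_real_
  )
  hot <- derive_flags(onset(5), w)
  expect_true(hot$heat_wave)
  expect_true(hot$tropical_night)
  expect_equal(hot$wbgt_max,
               max(daily_summaries(w)$wbgt_max[5]))

  cool <- derive_flags(onset(8), w)
  expect_false(cool$heat_wave)
  expect_false(cool$tropical_night)

  # re-deriving on an already-derived case changes nothing
  expect_equal(derive_flags(hot, w), hot)

  # insufficient coverage names the missing days
  expect_error(derive_flags(onset(2), w), "2013-06-29",
               class = "heatstrain_coverage_error")

  # incomplete night window leaves tropical_night indeterminate
  w_trunc <- w[w$timestamp >= as.POSIXct("2013-07-01 03:00", tz = "UTC"), ]
  d_trunc <- daily_summaries(w_trunc)
  expect_true(is.na(d_trunc$night_tmin[1]))
})
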