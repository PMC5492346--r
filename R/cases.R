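#' Read a worker-case table
#'
#' Reads the case CSV schema `case_id, age, heavy_exertion, unacclimatized,
#' onset_date, tropical_night, heat_wave, wbgt_max`. Flag columns accept
#' `0`/`1`, `TRUE`/`FALSE`, or the `o`/`x` marks used in the published case
#' table (`o` = attribute present); an empty flag is kept as NA
#' (indeterminate). `unacclimatized` is TRUE for workers within their first
#' week of outdoor placement at illness onset.
#'
#' @param path Path to the CSV file (header mandatory).
#' @return A tibble of worker cases, one row per case.
#' @seealso [write_cases()], [heat_cases()]
#' @export
read_cases <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  assert_columns(df, c("case_id", "age", "heavy_exertion", "unacclimatized",
                       "onset_date", "tropical_night", "heat_wave", "wbgt_max"),
                 sprintf("case file '%s'", path))
  if (nrow(df) == 0) {
    return(tibble::tibble(
      case_id = character(), age = numeric(), heavy_exertion = logical(),
      unacclimatized = logical(), onset_date = as.Date(character()),
      tropical_night = logical(), heat_wave = logical(), wbgt_max = numeric()
    ))
  }
  num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("unparsable %s at row %d: '%s'", col, bad[1], x[bad[1]]),
            class = "heatstrain_schema_error")
    }
    out
  }
  ages <- num(df$age, "age")
  bad_age <- which(!is.na(ages) & (ages < 15 | ages > 100))
  if (length(bad_age) > 0) {
    abort(sprintf("age outside [15, 100] at row %d", bad_age[1]),
          class = "heatstrain_schema_error")
  }
  tibble::tibble(
    case_id = df$case_id,
    age = ages,
    heavy_exertion = parse_flag(df$heavy_exertion, "heavy_exertion"),
    unacclimatized = parse_flag(df$unacclimatized, "unacclimatized"),
    onset_date = lubridate::as_date(dplyr::na_if(df$onset_date, "")),
    tropical_night = parse_flag(df$tropical_night, "tropical_night"),
    heat_wave = parse_flag(df$heat_wave, "heat_wave"),
    wbgt_max = num(df$wbgt_max, "wbgt_max")
  )
}

parse_flag <- function(x, col) {
  key <- tolower(trimws(x))
  out <- dplyr::case_when(
    is.na(key) | key == "" ~ NA,
    key %in% c("1", "true", "o", "yes") ~ TRUE,
    key %in% c("0", "false", "x", "no") ~ FALSE,
    .default = NA
  )
  bad <- which(!is.na(key) & key != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("unparsable flag %s at row %d: '%s'", col, bad[1], x[bad[1]]),
          class = "heatstrain_schema_error")
  }
  out
}

#' Write a worker-case table
#'
#' Flags are written as `0`/`1` (empty for indeterminate); reading the file
#' back with [read_cases()] reproduces the input exactly.
#'
#' @param cases Worker-case tibble as returned by [read_cases()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  flag01 <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x))
  out <- tibble::tibble(
    case_id = cases$case_id,
    age = cases$age,
    heavy_exertion = flag01(cases$heavy_exertion),
    unacclimatized = flag01(cases$unacclimatized),
    onset_date = format(cases$onset_date, "%Y-%m-%d"),
    tropical_night = flag01(cases$tropical_night),
    heat_wave = flag01(cases$heat_wave),
    wbgt_max = cases$wbgt_max
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# md5 of the packaged case table; guards against silent fixture corruption
.table1_md5 <- "259d73f5f6cf18b28586afe734bfe601"

#' The packaged 47-case table of compensated heat-related illnesses
#'
#' Loads the package's transcription of the published table of 47
#' compensated occupational heat-related illness cases in Korean outdoor
#' workers (2010-2014): age, heavy-exertion and acclimatization status,
#' tropical-night and heat-wave exposure flags, and the maximum estimated
#' WBGT (degrees C) around onset. The file's checksum is verified before
#' parsing.
#'
#' @return A 47-row worker-case tibble.
#' @examples
#' nrow(heat_cases())
#' @export
heat_cases <- function() {
  path <- system.file("extdata", "table1_cases.csv",
                      package = "heatstrain", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .table1_md5)) {
    abort("packaged case table failed its integrity checksum",
          class = "heatstrain_integrity_error")
  }
  read_cases(path)
}

#' Derive exposure flags for cases from station weather
#'
#' For each case with an onset date, fills in from the weather series:
#' `tropical_night` (was the night immediately preceding the onset day's
#' morning tropical?), `heat_wave` (does the onset day fall inside a
#' detected heat-wave episode?) and `wbgt_max` (maximum valid estimated WBGT
#' over the onset day, or over `wbgt_window_days` calendar days ending at
#' onset). Re-deriving with the same weather and settings is idempotent.
#'
#' @param cases Worker-case tibble; `onset_date` must be present.
#' @param weather A `meteo_series` covering each onset date and at least the
#'   3 days before it.
#' @param hw_threshold,hw_min_run Heat-wave rule parameters
#'   (see [detect_heat_waves()]).
#' @param tn_threshold Tropical-night threshold, degrees C.
#' @param night_start,night_end,night_min_coverage Night-window settings
#'   (see [daily_summaries()]).
#' @param wbgt_window_days Number of calendar days (ending at onset)
#'   over which `wbgt_max` is taken; default 1 = onset day only.
#' @return The case tibble with the three derived columns filled.
#' @export
derive_flags <- function(cases, weather,
                         hw_threshold = 33, hw_min_run = 2L,
                         tn_threshold = 25,
                         night_start = 18L, night_end = 9L,
                         night_min_coverage = 0.75,
                         wbgt_window_days = 1L) {
  if (anyNA(cases$onset_date)) {
    abort("every case needs an onset_date to derive flags",
          class = "heatstrain_schema_error")
  }
  daily <- daily_summaries(weather, night_start = night_start,
                           night_end = night_end,
                           night_min_coverage = night_min_coverage)
  need <- sort(unique(unlist(
    lapply(cases$onset_date, function(d) as.character(d - 3:0))
  )))
  missing_days <- setdiff(need, as.character(daily$date))
  if (length(missing_days) > 0) {
    abort(sprintf(
      "weather does not cover onset windows; missing day(s): %s",
      paste(missing_days, collapse = ", ")
    ), class = "heatstrain_coverage_error")
  }
  episodes <- detect_heat_waves(daily, threshold = hw_threshold,
                                min_run = hw_min_run)
  idx <- match(cases$onset_date, daily$date)
  wbgt_win <- vapply(cases$onset_date, function(d) {
    w <- daily$wbgt_max[daily$date >= d - (wbgt_window_days - 1L) &
                          daily$date <= d]
    if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE)
  }, numeric(1))
  cases$tropical_night <- is_tropical_night(daily$night_tmin[idx],
                                            threshold = tn_threshold)
  cases$heat_wave <- in_heat_wave(cases$onset_date, episodes)
  cases$wbgt_max <- wbgt_win
  cases
}

#' Classify cases against an exposure-limit table
#'
#' Assigns each case its metabolic-rate class (heavy exertion -> high,
#' otherwise moderate), looks up the WBGT limit for its acclimatization
#' status, and tests whether the case's maximum estimated WBGT reached that
#' limit (inclusive).
#'
#' @param cases Worker-case tibble with `wbgt_max` present for every row.
#' @param table Limit table; defaults to [default_limit_table()].
#' @return A tibble aligned with `cases`: `case_id`, `mclass`, `limit_c`,
#'   `exceeds`.
#' @export
classify_cases <- function(cases, table = default_limit_table()) {
  if (nrow(cases) == 0) {
    abort("no cases to classify", class = "heatstrain_empty_input")
  }
  if (anyNA(cases$wbgt_max)) {
    abort(sprintf("wbgt_max missing for case(s): %s",
                  paste(cases$case_id[is.na(cases$wbgt_max)], collapse = ", ")),
          class = "heatstrain_incomplete_case")
  }
  mclass <- metabolic_class(cases$heavy_exertion)
  limit <- get_limit(!cases$unacclimatized, mclass, table)
  tibble::tibble(
    case_id = cases$case_id,
    mclass = mclass,
    limit_c = limit,
    exceeds = cases$wbgt_max >= limit
  )
}

#' Summarize a case cohort
#'
#' Counts and percentages (1 decimal, half-up, matching how the cohort
#' results are printed) for the exposure and personal factors: heat wave,
#' tropical night, unacclimatized, heavy exertion, and — when a
#' classification is supplied — WBGT limit exceedance. Indeterminate (NA)
#' flags count as absent and are reported separately. Ages are binned into
#' decades 20s through 70s.
#'
#' @param cases Worker-case tibble.
#' @param classifications Optional classification tibble from
#'   [classify_cases()], aligned with `cases` by `case_id`.
#' @return A `cohort_summary` object: list with `n_total`, a `factors`
#'   tibble (`measure`, `count`, `pct`, `n_indeterminate`) and an
#'   `age_decades` tibble (`decade`, `count`, `pct`).
#' @examples
#' cases <- heat_cases()
#' summarize_cohort(cases, classify_cases(cases))
#' @export
summarize_cohort <- function(cases, classifications = NULL) {
  n <- nrow(cases)
  if (n == 0) {
    abort("cannot summarize an empty cohort", class = "heatstrain_empty_input")
  }
  flags <- list(
    heat_wave = cases$heat_wave,
    tropical_night = cases$tropical_night,
    unacclimatized = cases$unacclimatized,
    heavy_exertion = cases$heavy_exertion
  )
  if (!is.null(classifications)) {
    stopifnot(identical(classifications$case_id, cases$case_id))
    flags$exceeds_limit <- classifications$exceeds
  }
  factors <- tibble::tibble(
    measure = names(flags),
    count = vapply(flags, function(f) sum(f, na.rm = TRUE), 1L,
                   USE.NAMES = FALSE),
    pct = vapply(flags, function(f) pct(sum(f, na.rm = TRUE), n), 1.0,
                 USE.NAMES = FALSE),
    n_indeterminate = vapply(flags, function(f) sum(is.na(f)), 1L,
                             USE.NAMES = FALSE)
  )
  decade_bin <- cut(cases$age, breaks = seq(20, 80, 10), right = FALSE,
                    labels = paste0(seq(20, 70, 10), "s"))
  decade_counts <- as.integer(table(decade_bin))
  decades <- tibble::tibble(
    decade = levels(decade_bin),
    count = decade_counts,
    pct = pct(decade_counts, n)
  )
  structure(
    list(n_total = n, factors = factors, age_decades = decades),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d heat-related illness cases\n", x$n_total))
  for (i in seq_len(nrow(x$factors))) {
    r <- x$factors[i, ]
    cat(sprintf("  %-15s %2d/%d (%.1f%%)%s\n", r$measure, r$count, x$n_total,
                r$pct,
                if (r$n_indeterminate > 0)
                  sprintf(" [%d indeterminate]", r$n_indeterminate) else ""))
  }
  cat("  age decades:   ",
      paste(sprintf("%s:%d", x$age_decades$decade, x$age_decades$count),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a cohort summary to JSON and CSV
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param json_path,csv_path Output paths; either may be NULL to skip.
#' @return Invisibly, the list written to JSON.
#' @export
write_summary <- function(summary, json_path = NULL, csv_path = NULL) {
  payload <- list(
    n_total = summary$n_total,
    factors = summary$factors,
    age_decades = summary$age_decades
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    flat <- dplyr::bind_rows(
      summary$factors |> dplyr::select("measure", "count", "pct"),
      summary$age_decades |>
        dplyr::transmute(measure = paste0("age_", .data$decade),
                         count = .data$count, pct = .data$pct)
    )
    readr::write_csv(flat, csv_path)
  }
  invisible(payload)
}
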