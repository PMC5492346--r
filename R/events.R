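#' Per-calendar-day aggregates of an hourly weather series
#'
#' Computes, for every calendar day with at least one observation: the daily
#' maximum dry-bulb temperature `tmax`, the minimum temperature over the
#' night window ending on that day's morning (`night_tmin`), and the daily
#' maximum estimated WBGT over hours inside the estimation envelope
#' (`wbgt_max`, NA when no valid hour exists).
#'
#' The night window runs from `night_start` o'clock on the previous calendar
#' day to `night_end` o'clock on the current day (both inclusive), so a
#' tropical-night flag on date d describes the night immediately preceding
#' d's daytime. `night_tmin` requires at least `night_min_coverage` of the
#' window's nominal hours to be observed; otherwise it is NA (indeterminate)
#' rather than a min over a fragment — the first day of a series is
#' therefore usually indeterminate.
#'
#' `tmax`, by contrast, is taken over whatever hours exist: a daily maximum
#' is robust to gaps in a way a minimum over a truncated night is not.
#'
#' @param series A `meteo_series`.
#' @param night_start Hour (0-23) the night window opens on the previous day.
#' @param night_end Hour (0-23) the window closes on the current day.
#' @param night_min_coverage Minimum observed fraction of nominal night-window
#'   hours for `night_tmin` to be reported.
#' @return A tibble with columns `date`, `tmax`, `night_tmin`, `wbgt_max`,
#'   `n_obs`, `n_night_obs`, one row per observed calendar day, date-sorted.
#' @export
daily_summaries <- function(series, night_start = 18L, night_end = 9L,
                            night_min_coverage = 0.75) {
  stopifnot(night_start %in% 0:23, night_end %in% 0:23,
            night_start > night_end) # window must wrap midnight
  est <- series_wbgt(series)
  date <- lubridate::as_date(est$timestamp)
  hour <- lubridate::hour(est$timestamp)

  day_tab <- est |>
    dplyr::mutate(date = date) |>
    dplyr::group_by(date) |>
    dplyr::summarise(
      tmax = max(.data$ta),
      wbgt_max = if (any(.data$valid)) max(.data$wbgt[.data$valid]) else NA_real_,
      n_obs = dplyr::n(),
      .groups = "drop"
    )

  # attach each observation's hour to the night it belongs to (the window
  # ending on `night_date`'s morning), then aggregate
  in_evening <- hour >= night_start
  in_morning <- hour <= night_end
  night_date <- dplyr::case_when(
    in_evening ~ date + 1L,
    in_morning ~ date,
    .default = lubridate::as_date(NA)
  )
  nominal_hours <- (24L - night_start) + (night_end + 1L)
  night_tab <- tibble::tibble(night_date = night_date, ta = est$ta,
                              hour = hour) |>
    dplyr::filter(!is.na(night_date)) |>
    dplyr::group_by(.data$night_date) |>
    dplyr::summarise(
      night_tmin = min(.data$ta),
      n_night_obs = length(unique(.data$hour)),
      .groups = "drop"
    ) |>
    dplyr::mutate(night_tmin = ifelse(
      .data$n_night_obs >= night_min_coverage * nominal_hours,
      .data$night_tmin, NA_real_
    ))

  day_tab |>
    dplyr::left_join(night_tab, by = c(date = "night_date")) |>
    dplyr::mutate(n_night_obs = dplyr::coalesce(.data$n_night_obs, 0L)) |>
    dplyr::select("date", "tmax", "night_tmin", "wbgt_max",
                  "n_obs", "n_night_obs") |>
    dplyr::arrange(date)
}

#' Detect heat-wave episodes in daily summaries
#'
#' A heat-wave episode is a maximal run of at least `min_run` consecutive
#' calendar days whose daily maximum temperature reaches `threshold`
#' (inclusive: a 33.0 degree day qualifies under the default Korean advisory
#' definition). A missing calendar day, or a day with missing `tmax`, breaks
#' a run — absent weather is never assumed hot.
#'
#' @param summaries Daily summary tibble from [daily_summaries()] (only
#'   `date` and `tmax` are used), sorted by date.
#' @param threshold Qualifying daily-maximum temperature, degrees C.
#' @param min_run Minimum number of consecutive qualifying days.
#' @return Tibble of episodes: `start_date`, `end_date` (inclusive),
#'   `n_days`, `peak_tmax`. Zero rows when none found.
#' @examples
#' d <- tibble::tibble(
#'   date = as.Date("2013-08-01") + 0:3,
#'   tmax = c(32, 33.5, 34, 31)
#' )
#' detect_heat_waves(d)
#' @export
detect_heat_waves <- function(summaries, threshold = 33, min_run = 2L) {
  assert_columns(summaries, c("date", "tmax"), "daily summaries")
  if (nrow(summaries) == 0) {
    return(empty_episodes())
  }
  d <- as.integer(summaries$date)
  if (is.unsorted(d, strictly = TRUE)) {
    abort("daily summaries must be sorted by date without duplicates",
          class = "heatstrain_order_error")
  }
  hot <- !is.na(summaries$tmax) & summaries$tmax >= threshold
  keep <- which(hot)
  if (length(keep) == 0) {
    return(empty_episodes())
  }
  # group qualifying days into runs of consecutive calendar dates; a missing
  # day shows up as a date gap > 1 and breaks the run
  run_id <- cumsum(c(1L, diff(d[keep]) != 1L))
  runs <- split(keep, run_id)
  runs <- runs[vapply(runs, length, 1L) >= min_run]
  if (length(runs) == 0) {
    return(empty_episodes())
  }
  runs <- unname(runs)
  tibble::tibble(
    start_date = summaries$date[vapply(runs, min, 1L)],
    end_date = summaries$date[vapply(runs, max, 1L)],
    n_days = vapply(runs, length, 1L),
    peak_tmax = vapply(runs, function(i) max(summaries$tmax[i]), 1.0)
  ) |> dplyr::arrange(.data$start_date)
}

empty_episodes <- function() {
  tibble::tibble(
    start_date = as.Date(character()), end_date = as.Date(character()),
    n_days = integer(), peak_tmax = numeric()
  )
}

#' Which dates fall inside a heat-wave episode?
#'
#' @param dates Date vector to test.
#' @param episodes Episode tibble from [detect_heat_waves()].
#' @return Logical vector: TRUE where the date lies inside some episode's
#'   inclusive span.
#' @export
in_heat_wave <- function(dates, episodes) {
  if (nrow(episodes) == 0) {
    return(rep(FALSE, length(dates)))
  }
  vapply(
    as.integer(dates),
    function(d) any(d >= as.integer(episodes$start_date) &
                      d <= as.integer(episodes$end_date)),
    logical(1)
  )
}

#' Tropical-night test
#'
#' TRUE when the night minimum stays strictly above the threshold ("above
#' 25 degrees C" is strict: a 25.0 minimum is not tropical). An absent night
#' minimum (incomplete window) yields NA — indeterminate, distinct from
#' FALSE.
#'
#' @param night_tmin Night-window minimum temperature(s), degrees C; NA for
#'   indeterminate nights.
#' @param threshold Tropical-night threshold, degrees C.
#' @return Logical vector with NA propagated.
#' @export
is_tropical_night <- function(night_tmin, threshold = 25) {
  night_tmin > threshold
}
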