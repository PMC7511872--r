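## Heart-rate preprocessing: analysis-window trimming, physiological
## artifact filtering, hourly aggregation and cohort inclusion criteria.

#' Trim minute records to the analysis window
#'
#' Retains records from Friday 00:00 (inclusive) through Monday 16:00
#' (exclusive) of the recording week: Thursday run-in data and everything
#' from Monday 16:00 onward are removed, so all subjects cover the same
#' 88-hour window regardless of when on Thursday they started.
#'
#' @param minutes Minute tibble with `subject_id` and `timestamp`.
#' @return The trimmed tibble; subjects with no records inside the window
#'   are reported in the `exclusions` attribute (`subject_id`, `reason`).
#' @export
trim_window <- function(minutes) {
  wd <- wday(minutes$timestamp, week_start = 1)  # Mon = 1 ... Sun = 7
  keep <- wd %in% c(5, 6, 7) | (wd == 1 & hour(minutes$timestamp) < 16)
  out <- minutes[keep, , drop = FALSE]
  dropped <- setdiff(unique(minutes$subject_id), unique(out$subject_id))
  if (length(dropped) > 0) {
    inform(sprintf("trim_window: dropped %d subject(s) with no data in the analysis window.",
                   length(dropped)))
  }
  attr(out, "exclusions") <- tibble(subject_id = dropped,
                                    reason = "no data in analysis window")
  out
}

#' Age-predicted maximum heart rate
#'
#' The age-predicted ceiling `208 - 0.7 * age` bpm used as the upper
#' plausibility bound for measured heart rate.
#'
#' @param age Age in years, > 0.
#' @return Maximum plausible HR in bpm.
#' @export
#' @examples
#' tanaka_max_hr(40)  # 180
tanaka_max_hr <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    abort("`age` must be positive and finite.",
          class = "circastress_domain_error")
  }
  208 - 0.7 * age
}

#' Flag implausible heart-rate minutes
#'
#' Two conjunctive artifact filters applied to malfunction-cleaned minute
#' HR, per subject: (1) values outside the subject's median +/- k x SD band
#' (median and SD computed over the subject's malfunction-cleaned minutes in
#' the analysis window, so the filter is idempotent); (2) values below the
#' 30 bpm floor or above the age-predicted [tanaka_max_hr()] ceiling. The
#' stated order matters and is fixed: the band is computed first, then the
#' absolute bounds are applied.
#'
#' Rows flagged as malfunction or with missing HR are never valid. Subjects
#' left with fewer than two filterable minutes are dropped (reported in the
#' `exclusions` attribute).
#'
#' @param minutes Minute tibble; must carry `is_malfunction` (see
#'   [flag_malfunction()]) and `hr_bpm`.
#' @param profiles Subject profiles (for age).
#' @param config A [filter_config()].
#' @return The input with a logical `hr_valid` column.
#' @export
filter_hr <- function(minutes, profiles, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (!"is_malfunction" %in% names(minutes)) {
    abort("`minutes` must carry `is_malfunction`; run flag_malfunction() first.",
          class = "circastress_spec_error")
  }
  validate_profiles(profiles)
  unknown <- setdiff(unique(minutes$subject_id), profiles$subject_id)
  if (length(unknown) > 0) {
    abort(sprintf("Minutes reference unknown subject(s): %s.",
                  paste(head(unknown, 3), collapse = ", ")),
          class = "circastress_spec_error")
  }
  out <- minutes |>
    mutate(.clean = !is.na(hr_bpm) &
             !if_else(is.na(is_malfunction), TRUE, is_malfunction)) |>
    left_join(select(profiles, subject_id, age), by = "subject_id") |>
    group_by(subject_id) |>
    mutate(
      .m = median(hr_bpm[.data$.clean]),
      .s = sd(hr_bpm[.data$.clean]),
      .n_clean = sum(.data$.clean)
    ) |>
    ungroup() |>
    mutate(
      .s = if_else(is.na(.data$.s), 0, .data$.s),  # single-minute subjects
      hr_valid = .data$.clean &
        hr_bpm >= .data$.m - config$sd_multiplier * .data$.s &
        hr_bpm <= .data$.m + config$sd_multiplier * .data$.s &
        hr_bpm >= config$hr_floor &
        hr_bpm <= tanaka_max_hr(age)
    )
  dropped <- out |>
    distinct(subject_id, .data$.n_clean) |>
    filter(.data$.n_clean < 2) |>
    pull(subject_id)
  out <- out |>
    filter(!subject_id %in% dropped) |>
    select(-".clean", -".m", -".s", -".n_clean", -"age")
  if (length(dropped) > 0) {
    inform(sprintf("filter_hr: dropped %d subject(s) with fewer than 2 clean minutes.",
                   length(dropped)))
  }
  attr(out, "exclusions") <- tibble(subject_id = dropped,
                                    reason = "fewer than 2 clean minutes")
  out
}

#' Aggregate valid minutes to hourly observations
#'
#' Pools each subject's valid minutes by hour of day (0-23) and day-type
#' (workday = Friday/Monday, weekend = Saturday/Sunday) and emits the full
#' 48-cell grid per subject: `mean_hr` is the mean of the pooled valid
#' minute HR, left missing for cells with fewer than
#' `min_valid_minutes_per_hour` valid minutes (the model later drops
#' missing rows).
#'
#' @param minutes Output of [filter_hr()] (needs `hr_valid`).
#' @param config A [filter_config()].
#' @return Tibble: `subject_id`, `hour_of_day`, `is_weekend`, `mean_hr`,
#'   `n_minutes`.
#' @export
aggregate_hourly <- function(minutes, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  minutes |>
    mutate(hour_of_day = hour(timestamp),
           is_weekend = weekend01_of(timestamp) == 1L) |>
    group_by(subject_id, hour_of_day, is_weekend) |>
    summarise(mean_hr = mean(hr_bpm[hr_valid]),
              n_minutes = sum(hr_valid), .groups = "drop") |>
    complete(subject_id, hour_of_day = 0:23, is_weekend = c(FALSE, TRUE),
             fill = list(n_minutes = 0L)) |>
    mutate(mean_hr = if_else(n_minutes >= config$min_valid_minutes_per_hour,
                             mean_hr, NA_real_),
           n_minutes = as.integer(n_minutes)) |>
    arrange(subject_id, is_weekend, hour_of_day)
}

#' Apply the cohort inclusion criterion
#'
#' A subject is retained only with at least `min_hours_per_daytype`
#' (default 24) valid calendar hour-slots on workdays AND on weekend days.
#' Hour-slots are counted per calendar hour (subject x date x hour, before
#' pooling across days): a slot is valid when it has at least
#' `min_valid_minutes_per_hour` valid minutes. A day-type can therefore
#' contribute up to 40 workday slots (Friday 24 + Monday 16) and 48
#' weekend slots.
#'
#' @param hourly Output of [aggregate_hourly()].
#' @param minutes Output of [filter_hr()] (calendar information).
#' @param config A [filter_config()].
#' @return The hourly table restricted to included subjects; excluded
#'   subjects are reported in the `exclusions` attribute.
#' @export
apply_inclusion <- function(hourly, minutes, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  slots <- minutes |>
    filter(hr_valid) |>
    mutate(date = as_date(timestamp), hour_of_day = hour(timestamp),
           is_weekend = weekend01_of(timestamp) == 1L) |>
    count(subject_id, date, hour_of_day, is_weekend, name = "n_valid") |>
    filter(n_valid >= config$min_valid_minutes_per_hour) |>
    count(subject_id, is_weekend, name = "n_slots")
  status <- tibble(subject_id = unique(hourly$subject_id)) |>
    left_join(pivot_wider(slots, names_from = is_weekend,
                          values_from = n_slots,
                          names_prefix = "we_"), by = "subject_id") |>
    mutate(across(any_of(c("we_FALSE", "we_TRUE")), ~replace_na(.x, 0L)))
  if (!"we_FALSE" %in% names(status)) status$we_FALSE <- 0L
  if (!"we_TRUE" %in% names(status)) status$we_TRUE <- 0L
  excluded <- status |>
    filter(.data$we_FALSE < config$min_hours_per_daytype |
             .data$we_TRUE < config$min_hours_per_daytype) |>
    mutate(reason = sprintf("only %d workday / %d weekend valid hours",
                            .data$we_FALSE, .data$we_TRUE)) |>
    select(subject_id, reason)
  out <- filter(hourly, !subject_id %in% excluded$subject_id)
  attr(out, "exclusions") <- excluded
  out
}

#' Preprocess minute streams end to end
#'
#' Convenience wrapper running the whole preprocessing chain in the fixed
#' order: trim to the Friday 00:00 - Monday 16:00 window, flag
#' accelerometer malfunction minutes, filter implausible HR (median +/- 3SD
#' band, 30 bpm floor, age-predicted ceiling), aggregate to hourly
#' observations, and apply the 24-hours-per-day-type inclusion criterion.
#'
#' @param minutes Raw minute tibble (with accelerometer features).
#' @param profiles Subject profiles.
#' @param config A [filter_config()].
#' @return List with `hourly` (analysis table), `minutes` (flagged minute
#'   table) and `exclusions` (subject, reason).
#' @export
preprocess_minutes <- function(minutes, profiles, config = filter_config()) {
  trimmed <- trim_window(minutes)
  excl <- attr(trimmed, "exclusions")
  flagged <- flag_malfunction(trimmed)
  filtered <- filter_hr(flagged, profiles, config)
  excl <- bind_rows(excl, attr(filtered, "exclusions"))
  hourly <- aggregate_hourly(filtered, config)
  hourly <- apply_inclusion(hourly, filtered, config)
  excl <- bind_rows(excl, attr(hourly, "exclusions"))
  attr(hourly, "exclusions") <- NULL
  list(hourly = hourly, minutes = filtered, exclusions = excl)
}
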