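## Reporting plots: hourly HR profiles, and per-hour age / PSS slope panels
## derived from the fitted model.

#' Hourly heart-rate profiles by gender and day-type
#'
#' Plots the cohort mean HR per hour of day, split by gender and day-type,
#' with subject-level normal-approximation 95% confidence bars. Points sit
#' at the middle of each hour bin.
#'
#' @param hourly Hourly observation table.
#' @param subjects Subject profiles.
#' @return A ggplot object.
#' @export
plot_hour_profiles <- function(hourly, subjects) {
  dat <- hourly |>
    filter(!is.na(mean_hr)) |>
    inner_join(select(subjects, subject_id, gender), by = "subject_id") |>
    group_by(gender, is_weekend, hour_of_day) |>
    summarise(hr = mean(mean_hr), se = sd(mean_hr) / sqrt(n()),
              .groups = "drop") |>
    mutate(daytype = if_else(is_weekend, "weekend", "workday"))
  ggplot(dat, aes(x = hour_of_day + 0.5, y = hr, colour = gender)) +
    geom_line() +
    geom_pointrange(aes(ymin = hr - 1.96 * se, ymax = hr + 1.96 * se),
                    size = 0.2) +
    facet_wrap(~daytype) +
    labs(x = "Hour of day", y = "Heart rate (bpm)", colour = "Gender") +
    theme_minimal()
}

## Model-implied per-hour slope of HR in a covariate, with delta-method SEs.
## The slope at hour t is a linear contrast c(t)' beta over the columns that
## involve the covariate.
covariate_hour_slopes <- function(fit, covariate, moderator01) {
  cols <- names(fit$beta)
  involves <- map_lgl(strsplit(cols, ":", fixed = TRUE),
                      ~ covariate %in% .x)
  hours <- 0:23
  t <- hours + 0.5
  rows <- map(hours, function(h) {
    tt <- h + 0.5
    contrast <- setNames(numeric(length(cols)), cols)
    for (cn in cols[involves]) {
      parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
      others <- setdiff(parts, covariate)
      val <- 1
      for (o in others) {
        val <- val * switch(o,
          sin24 = sin(2 * pi * tt / 24), cos24 = cos(2 * pi * tt / 24),
          sin12 = sin(2 * pi * tt / 12), cos12 = cos(2 * pi * tt / 12),
          sin8 = sin(2 * pi * tt / 8), cos8 = cos(2 * pi * tt / 8),
          sin6 = sin(2 * pi * tt / 6), cos6 = cos(2 * pi * tt / 6),
          weekend = moderator01[["weekend"]] %||% 0,
          gender = moderator01[["gender"]] %||% 0,
          abort(sprintf("Unexpected factor `%s` in column `%s`.", o, cn)))
      }
      contrast[cn] <- val
    }
    est <- sum(contrast * fit$beta)
    se <- sqrt(as.numeric(t(contrast) %*% fit$cov_beta %*% contrast))
    tibble(hour_of_day = h, slope = est, se = se)
  })
  bind_rows(rows)
}

#' Per-hour age slopes by day-type
#'
#' Model-implied change of HR per year of age at every hour of the day,
#' split for workdays and weekend days, with 95% Wald bands.
#'
#' @param fit A [fit_harmonic_model()] result including the age terms.
#' @return A ggplot object; the underlying table is in the `data` slot.
#' @export
plot_age_slopes <- function(fit) {
  dat <- bind_rows(
    mutate(covariate_hour_slopes(fit, "age", list(weekend = 0)),
           daytype = "workday"),
    mutate(covariate_hour_slopes(fit, "age", list(weekend = 1)),
           daytype = "weekend")
  )
  ggplot(dat, aes(x = hour_of_day + 0.5, y = slope)) +
    geom_ribbon(aes(ymin = slope - 1.96 * se, ymax = slope + 1.96 * se),
                alpha = 0.2) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~daytype) +
    labs(x = "Hour of day", y = "HR slope (bpm per year of age)") +
    theme_minimal()
}

#' Per-hour PSS slopes by gender
#'
#' Model-implied change of HR per PSS point at every hour of the day, split
#' for male and female subjects, with 95% Wald bands.
#'
#' @param fit A [fit_harmonic_model()] result including the PSS terms.
#' @return A ggplot object.
#' @export
plot_pss_slopes <- function(fit) {
  dat <- bind_rows(
    mutate(covariate_hour_slopes(fit, "pss", list(gender = 0)),
           gender = "male"),
    mutate(covariate_hour_slopes(fit, "pss", list(gender = 1)),
           gender = "female")
  )
  ggplot(dat, aes(x = hour_of_day + 0.5, y = slope)) +
    geom_ribbon(aes(ymin = slope - 1.96 * se, ymax = slope + 1.96 * se),
                alpha = 0.2) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~gender) +
    labs(x = "Hour of day", y = "HR slope (bpm per PSS point)") +
    theme_minimal()
}

#' @export
autoplot.harmonic_fit <- function(object, ...) {
  amp <- harmonic_amplitudes(object)
  t <- seq(0, 24, by = 0.1)
  profile <- map(seq_len(nrow(amp)), function(i) {
    amp$amplitude[i] * cos(2 * pi * (t - amp$acrophase[i]) / amp$period[i])
  })
  pred <- object$beta[["intercept"]] + Reduce(`+`, profile)
  ggplot(tibble(t = t, pred = pred), aes(t, pred)) +
    geom_line() +
    labs(x = "Hour of day", y = "Predicted HR (bpm), reference stratum") +
    theme_minimal()
}
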