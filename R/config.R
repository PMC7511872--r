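## Configuration objects for the simulator and the preprocessing pipeline.
## All constructors validate eagerly and return classed lists so that a bad
## value fails at configuration time, not three stages into a pipeline run.

period_names <- c("h24", "h12", "h8", "h6")
harmonic_periods <- c(h24 = 24, h12 = 12, h8 = 8, h6 = 6)

check_num <- function(x, name, len = 1, lower = -Inf, upper = Inf,
                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric of length %d.", name, len),
          class = "circastress_config_error")
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    abort(sprintf("`%s` must lie in %s%g, %g].", name,
                  if (strict_lower) "(" else "[", lower, upper),
          class = "circastress_config_error")
  }
  invisible(x)
}

#' Cohort configuration
#'
#' Describes the demographic composition of a simulated cohort: how many
#' subjects, how many of them are female, and the (truncated) normal
#' distributions ages and PSS-10 scores are drawn from. The defaults encode
#' the composition of the office-worker cohort the package models: 328
#' subjects (142 female), age 38.9 (SD 10.2) years, PSS-10 13.7 (SD 6.0)
#' with the female stratum shifted two points above the male stratum.
#'
#' `pss_mean` is the cohort-level mean; the female/male strata are offset by
#' `pss_female_shift` around it so that the overall mean is preserved for any
#' gender mix.
#'
#' @param n_subjects Number of subjects.
#' @param n_female Number of female subjects (the rest are male).
#' @param age_mean,age_sd Normal parameters for age in years; draws are
#'   rounded and clipped to `age_range`.
#' @param age_range Allowed integer age range (years).
#' @param pss_mean,pss_sd Normal parameters for the PSS-10 total score;
#'   out-of-range draws are redrawn (not clipped) so no mass piles up at 0
#'   or 40.
#' @param pss_female_shift Points added to the female stratum mean (and
#'   proportionally subtracted from the male stratum) so the cohort mean
#'   stays at `pss_mean`.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(n_subjects = 10, n_female = 4, seed = 1)
cohort_config <- function(n_subjects = 328L,
                          n_female = 142L,
                          age_mean = 38.9,
                          age_sd = 10.2,
                          age_range = c(18L, 67L),
                          pss_mean = 13.7,
                          pss_sd = 6.0,
                          pss_female_shift = 2,
                          seed = 1L) {
  if (!is_scalar_integerish(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be a positive integer.",
          class = "circastress_config_error")
  }
  if (!is_scalar_integerish(n_female) || n_female < 0 || n_female > n_subjects) {
    abort("`n_female` must be an integer in [0, n_subjects].",
          class = "circastress_config_error")
  }
  check_num(age_mean, "age_mean")
  check_num(age_sd, "age_sd", lower = 0, strict_lower = TRUE)
  check_num(age_range, "age_range", len = 2)
  check_num(pss_mean, "pss_mean", lower = 0, upper = 40)
  check_num(pss_sd, "pss_sd", lower = 0, strict_lower = TRUE)
  check_num(pss_female_shift, "pss_female_shift")
  if (!is_scalar_integerish(seed)) {
    abort("`seed` must be an integer.", class = "circastress_config_error")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_female = as.integer(n_female),
    age_mean = age_mean, age_sd = age_sd,
    age_range = as.integer(age_range),
    pss_mean = pss_mean, pss_sd = pss_sd,
    pss_female_shift = pss_female_shift, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Effect configuration for the heart-rate generator
#'
#' Gathers every generative parameter of the simulated heart-rate process:
#' the baseline level, the four circadian harmonics (24/12/8/6 h periods,
#' amplitude/acrophase form), how the weekend, PSS and age modulate the
#' harmonics, the random-effect standard deviations, and the AR(1) noise.
#'
#' The covariate modulations act linearly on the 24 h amplitude: PSS with
#' opposite sign for men (positive) and women (negative), age flattening the
#' rhythm more on workdays than on weekend days. Modulations are centred at
#' `age_ref` / `pss_ref` so the default amplitudes describe an average
#' subject. Magnitudes of these modulations are synthetic defaults chosen to
#' be physiologically plausible; only their signs are anchored in the
#' literature the package follows.
#'
#' Noise comes in two flavours: minute-scale AR(1) noise (`ar1_rho`,
#' `resid_sd`, used by [simulate_minute_streams()]) and hourly-scale AR(1)
#' noise (`ar1_rho_hourly`, `resid_sd_hourly`, used by [simulate_hourly()])
#' for exact parameter-recovery experiments — hourly averaging of minute
#' AR(1) noise is not itself AR(1), so recovery tests are only well-posed at
#' the hour scale. `resid_sd` is the stationary (marginal) SD of the noise.
#'
#' @param baseline_hr Baseline heart rate (bpm) of a male reference subject.
#' @param gender_shift Additive female minus male level shift (bpm).
#' @param harmonic_amplitudes Named vector (h24, h12, h8, h6) of amplitudes
#'   in bpm.
#' @param harmonic_phases Named vector of acrophases (hour of peak) in
#'   hours.
#' @param weekend_harmonic_delta Named vector of amplitude changes (bpm) on
#'   weekend days.
#' @param pss_h24_slope_male,pss_h24_slope_female 24 h amplitude change per
#'   PSS point (bpm/point).
#' @param age_h24_slope_workday,age_h24_slope_weekend 24 h amplitude change
#'   per year of age (bpm/year).
#' @param re_sd_intercept_subject SD (bpm) of the per-subject random
#'   intercept.
#' @param re_sd_intercept_daytype SD (bpm) of the per-subject-by-day-type
#'   random intercept.
#' @param re_sd_slopes Named vector (hour, h24, h12, h8, h6) of random-slope
#'   SDs.
#' @param ar1_rho Minute-scale AR(1) autocorrelation, in (-1, 1).
#' @param resid_sd Minute-scale stationary noise SD (bpm), > 0.
#' @param ar1_rho_hourly,resid_sd_hourly Hour-scale counterparts.
#' @param age_ref,pss_ref Centring constants (years, PSS points) for the
#'   covariate modulations.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(baseline_hr = 72.5,
                          gender_shift = 3.3,
                          harmonic_amplitudes = c(h24 = 6, h12 = 2, h8 = 1, h6 = 0.5),
                          harmonic_phases = c(h24 = 15, h12 = 13, h8 = 17, h6 = 11),
                          weekend_harmonic_delta = c(h24 = -1, h12 = -0.7, h8 = -0.3, h6 = -0.2),
                          pss_h24_slope_male = 0.08,
                          pss_h24_slope_female = -0.08,
                          age_h24_slope_workday = -0.06,
                          age_h24_slope_weekend = -0.02,
                          re_sd_intercept_subject = 7,
                          re_sd_intercept_daytype = 1.5,
                          re_sd_slopes = c(hour = 0.05, h24 = 1.5, h12 = 0.8, h8 = 0.5, h6 = 0.4),
                          ar1_rho = 0.9,
                          resid_sd = 3,
                          ar1_rho_hourly = 0.3,
                          resid_sd_hourly = 1.5,
                          age_ref = 38.9,
                          pss_ref = 13.7) {
  named4 <- function(x, name) {
    check_num(x, name, len = 4)
    if (!identical(names(x), period_names)) {
      abort(sprintf("`%s` must be named %s.", name,
                    paste(period_names, collapse = ", ")),
            class = "circastress_config_error")
    }
    x
  }
  check_num(baseline_hr, "baseline_hr", lower = 0, strict_lower = TRUE)
  check_num(gender_shift, "gender_shift")
  named4(harmonic_amplitudes, "harmonic_amplitudes")
  named4(harmonic_phases, "harmonic_phases")
  named4(weekend_harmonic_delta, "weekend_harmonic_delta")
  check_num(pss_h24_slope_male, "pss_h24_slope_male")
  check_num(pss_h24_slope_female, "pss_h24_slope_female")
  check_num(age_h24_slope_workday, "age_h24_slope_workday")
  check_num(age_h24_slope_weekend, "age_h24_slope_weekend")
  check_num(re_sd_intercept_subject, "re_sd_intercept_subject", lower = 0)
  check_num(re_sd_intercept_daytype, "re_sd_intercept_daytype", lower = 0)
  check_num(re_sd_slopes, "re_sd_slopes", len = 5, lower = 0)
  if (!identical(names(re_sd_slopes), c("hour", period_names))) {
    abort("`re_sd_slopes` must be named hour, h24, h12, h8, h6.",
          class = "circastress_config_error")
  }
  check_num(ar1_rho, "ar1_rho", lower = -1, upper = 1, strict_lower = TRUE)
  if (abs(ar1_rho) >= 1) abort("`ar1_rho` must satisfy |rho| < 1.",
                               class = "circastress_config_error")
  check_num(resid_sd, "resid_sd", lower = 0)
  check_num(ar1_rho_hourly, "ar1_rho_hourly", strict_lower = TRUE, lower = -1)
  if (abs(ar1_rho_hourly) >= 1) abort("`ar1_rho_hourly` must satisfy |rho| < 1.",
                                      class = "circastress_config_error")
  check_num(resid_sd_hourly, "resid_sd_hourly", lower = 0)
  check_num(age_ref, "age_ref")
  check_num(pss_ref, "pss_ref")
  structure(list(
    baseline_hr = baseline_hr, gender_shift = gender_shift,
    harmonic_amplitudes = harmonic_amplitudes,
    harmonic_phases = harmonic_phases,
    weekend_harmonic_delta = weekend_harmonic_delta,
    pss_h24_slope_male = pss_h24_slope_male,
    pss_h24_slope_female = pss_h24_slope_female,
    age_h24_slope_workday = age_h24_slope_workday,
    age_h24_slope_weekend = age_h24_slope_weekend,
    re_sd_intercept_subject = re_sd_intercept_subject,
    re_sd_intercept_daytype = re_sd_intercept_daytype,
    re_sd_slopes = re_sd_slopes,
    ar1_rho = ar1_rho, resid_sd = resid_sd,
    ar1_rho_hourly = ar1_rho_hourly, resid_sd_hourly = resid_sd_hourly,
    age_ref = age_ref, pss_ref = pss_ref
  ), class = "effect_config")
}

#' Null effect configuration
#'
#' Convenience wrapper: an [effect_config()] with every covariate modulation
#' (PSS, age, weekend) set to zero and, optionally, random slopes switched
#' off. Used for type-I-error experiments where the fitted PSS terms must be
#' truly null.
#'
#' @param slopes Keep the random-slope SDs (`TRUE`) or zero them (`FALSE`).
#' @param ... Passed on to [effect_config()].
#' @return An `effect_config`.
#' @export
null_effect_config <- function(slopes = FALSE, ...) {
  cfg <- effect_config(
    pss_h24_slope_male = 0, pss_h24_slope_female = 0,
    age_h24_slope_workday = 0, age_h24_slope_weekend = 0,
    weekend_harmonic_delta = c(h24 = 0, h12 = 0, h8 = 0, h6 = 0),
    ...
  )
  if (!slopes) cfg$re_sd_slopes[] <- 0
  cfg
}

#' Artifact configuration
#'
#' Rates and magnitudes of the measurement artifacts injected into simulated
#' minute streams: sensor-off episodes (patch removed or saturated: the
#' accelerometer features freeze and heart rate becomes garbage), spurious
#' heart-rate spikes, and dropped minutes.
#'
#' @param sensor_off_rate Expected sensor-off episodes per day.
#' @param sensor_off_duration Length-2 range (minutes) episode durations are
#'   drawn from uniformly.
#' @param spike_rate Expected spike artifacts per day.
#' @param spike_magnitude Spike size added to the true HR (bpm).
#' @param missing_minute_rate Fraction of minutes with no HR sample, in
#'   \[0, 1).
#' @return An object of class `artifact_config`.
#' @export
artifact_config <- function(sensor_off_rate = 0.5,
                            sensor_off_duration = c(120, 480),
                            spike_rate = 5,
                            spike_magnitude = 80,
                            missing_minute_rate = 0.02) {
  check_num(sensor_off_rate, "sensor_off_rate", lower = 0)
  check_num(sensor_off_duration, "sensor_off_duration", len = 2, lower = 1)
  if (sensor_off_duration[1] > sensor_off_duration[2]) {
    abort("`sensor_off_duration` must be an increasing range.",
          class = "circastress_config_error")
  }
  check_num(spike_rate, "spike_rate", lower = 0)
  check_num(spike_magnitude, "spike_magnitude")
  check_num(missing_minute_rate, "missing_minute_rate", lower = 0, upper = 1)
  if (missing_minute_rate >= 1) {
    abort("`missing_minute_rate` must be < 1.",
          class = "circastress_config_error")
  }
  structure(list(
    sensor_off_rate = sensor_off_rate,
    sensor_off_duration = sensor_off_duration,
    spike_rate = spike_rate, spike_magnitude = spike_magnitude,
    missing_minute_rate = missing_minute_rate
  ), class = "artifact_config")
}

#' No-artifact configuration
#'
#' An [artifact_config()] with all rates zero, for clean-signal experiments.
#' @return An `artifact_config`.
#' @export
no_artifacts <- function() {
  artifact_config(sensor_off_rate = 0, spike_rate = 0,
                  missing_minute_rate = 0)
}

#' Filtering configuration
#'
#' Thresholds used when cleaning minute-level heart rate: the absolute
#' floor (30 bpm), the median +/- `sd_multiplier` x SD plausibility band,
#' the minimum number of valid minutes an hour needs before its mean is
#' trusted, and the minimum hours of data per day-type for a subject to be
#' included.
#'
#' @param hr_floor Minimum plausible HR (bpm).
#' @param sd_multiplier Width of the median +/- k x SD band.
#' @param min_valid_minutes_per_hour Valid minutes an hour slot must have.
#' @param min_hours_per_daytype Valid calendar hour-slots required within
#'   each day-type for inclusion.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(hr_floor = 30,
                          sd_multiplier = 3,
                          min_valid_minutes_per_hour = 30L,
                          min_hours_per_daytype = 24L) {
  check_num(hr_floor, "hr_floor", lower = 0, strict_lower = TRUE)
  check_num(sd_multiplier, "sd_multiplier", lower = 0, strict_lower = TRUE)
  if (!is_scalar_integerish(min_valid_minutes_per_hour) ||
      min_valid_minutes_per_hour < 1 || min_valid_minutes_per_hour > 60) {
    abort("`min_valid_minutes_per_hour` must be an integer in [1, 60].",
          class = "circastress_config_error")
  }
  if (!is_scalar_integerish(min_hours_per_daytype) ||
      min_hours_per_daytype < 0) {
    abort("`min_hours_per_daytype` must be a non-negative integer.",
          class = "circastress_config_error")
  }
  structure(list(
    hr_floor = hr_floor, sd_multiplier = sd_multiplier,
    min_valid_minutes_per_hour = as.integer(min_valid_minutes_per_hour),
    min_hours_per_daytype = as.integer(min_hours_per_daytype)
  ), class = "filter_config")
}

## ACC malfunction indicator threshold (unitless summed absolute difference)
acc_malfunction_threshold <- 5e-4
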