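## Simulation of wearable minute streams and of hourly observations.
##
## Both simulators share one generative model: noise-free HR is the fixed
## design (amplitude/acrophase harmonics translated to sin/cos coefficients
## by true_fixed_effects()) plus subject random effects (intercepts per
## subject and per subject-by-day-type; hour/harmonic slopes per
## subject-by-day-type), and observed HR adds AR(1) noise — at minute
## resolution for the wearable stream, at hour resolution for the direct
## hourly simulator used in recovery experiments.

## Reference recording week: Thursday 08:00 through Monday 16:00 (exclusive).
recording_start <- function() as.POSIXct("2016-06-02 08:00:00", tz = "UTC")
recording_end <- function() as.POSIXct("2016-06-06 16:00:00", tz = "UTC")

## Decorrelated RNG stream per simulation stage. Passing the same integer to
## generate_cohort() and a stream simulator must not make the random effects
## replay the deviates that produced the covariates (which would alias
## random intercepts with age/PSS), so each simulator hashes its seed into
## its own stream.
stage_seed <- function(seed, stage) {
  m <- 2147483647
  x <- as.double(seed) %% m
  x <- (x * 48271) %% m          # exact: x * 48271 < 2^53
  x <- (x + stage * 1299709) %% m
  as.integer(x)
}

weekend01_of <- function(ts) as.integer(wday(ts, week_start = 1) >= 6)

## Random-effect draws for one cohort. Slope basis order: hour_c, then the
## sin/cos pair of each period.
draw_random_effects <- function(profiles, effects) {
  n <- nrow(profiles)
  slope_sd <- effects$re_sd_slopes[c("hour", rep(period_names, each = 2))]
  q <- length(slope_sd)
  draw_slopes <- function() {
    m <- matrix(rnorm(n * q), n, q) * rep(slope_sd, each = n)
    colnames(m) <- c("hour", paste0(c("sin", "cos"),
                                    rep(harmonic_periods, each = 2)))
    m
  }
  list(
    b0_subject = rnorm(n, 0, effects$re_sd_intercept_subject),
    b0_workday = rnorm(n, 0, effects$re_sd_intercept_daytype),
    b0_weekend = rnorm(n, 0, effects$re_sd_intercept_daytype),
    slopes_workday = draw_slopes(),
    slopes_weekend = draw_slopes()
  )
}

random_effects_tibble <- function(profiles, re) {
  wd <- as_tibble(re$slopes_workday)
  names(wd) <- paste0("workday_", names(wd))
  we <- as_tibble(re$slopes_weekend)
  names(we) <- paste0("weekend_", names(we))
  bind_cols(
    tibble(subject_id = profiles$subject_id,
           b0_subject = re$b0_subject,
           b0_workday = re$b0_workday,
           b0_weekend = re$b0_weekend),
    wd, we
  )
}

## Stationary AR(1) draws: marginal SD `sd`, lag-1 correlation `rho`.
ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  x0 <- rnorm(1, 0, sd)
  eps <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(eps, rho, method = "recursive", init = x0))
}

#' Simulate minute-level wearable streams for a cohort
#'
#' Produces one record per minute from Thursday 08:00 through Monday 15:59
#' for every subject: observed heart rate (noise-free circadian signal plus
#' minute-scale AR(1) noise), the three per-minute accelerometer features
#' (`mxyz`, `avgm`, `avgsd`), and a missing-HR flag. Measurement artifacts
#' are injected per the [artifact_config()]: sensor-off episodes freeze the
#' accelerometer features at zero and replace HR with garbage values, spike
#' artifacts add a large positive offset to single minutes, and missing
#' minutes drop the HR sample.
#'
#' @param profiles Subject profile tibble from [generate_cohort()].
#' @param effects An [effect_config()].
#' @param artifacts An [artifact_config()].
#' @param seed Integer seed; the same seed reproduces the streams
#'   bit-for-bit.
#' @return A list with `minutes` (tibble: `subject_id`, `timestamp`,
#'   `hr_bpm`, `mxyz`, `avgm`, `avgsd`, `hr_missing`, plus the noise-free
#'   `hr_true`) and `truth` (the effect config, the realized per-subject
#'   random effects, and the implied fixed-effect vector).
#' @export
simulate_minute_streams <- function(profiles,
                                    effects = effect_config(),
                                    artifacts = artifact_config(),
                                    seed = 1L) {
  validate_profiles(profiles)
  stopifnot(inherits(effects, "effect_config"),
            inherits(artifacts, "artifact_config"))
  times <- seq(recording_start(), recording_end() - 60, by = "1 min")
  m <- length(times)
  n <- nrow(profiles)
  n_days <- m / 1440
  t_day <- hour(times) + minute(times) / 60
  w01 <- weekend01_of(times)
  beta <- true_fixed_effects(effects)
  slope_basis <- cbind(t_day - 12, harmonic_basis(t_day))

  with_seed(stage_seed(seed, 1L), {
    re <- draw_random_effects(profiles, effects)
    hr_true <- matrix(0, m, n)
    hr_obs <- matrix(0, m, n)
    for (i in seq_len(n)) {
      df <- list(t = t_day, weekend01 = w01,
                 gender01 = rep(as.integer(profiles$gender[i] == "F"), m),
                 age_c = rep(profiles$age[i] - effects$age_ref, m),
                 pss_c = rep(profiles$pss[i] - effects$pss_ref, m))
      df <- as_tibble(df)
      X <- build_fixed_matrix(df, final_model_terms())
      sl <- slope_basis %*% t(re$slopes_workday[i, , drop = FALSE]) * (1 - w01) +
        slope_basis %*% t(re$slopes_weekend[i, , drop = FALSE]) * w01
      hr_true[, i] <- as.numeric(X %*% beta) + re$b0_subject[i] +
        (1 - w01) * re$b0_workday[i] + w01 * re$b0_weekend[i] +
        as.numeric(sl)
      hr_obs[, i] <- hr_true[, i] + ar1_noise(m, effects$ar1_rho,
                                              effects$resid_sd)
    }

    ## Accelerometer features during normal wear: around 1 g magnitude with
    ## minute-to-minute fluctuation well above the malfunction threshold.
    mxyz <- matrix(pmax(rnorm(m * n, 1.02, 0.03), 0), m, n)
    avgm <- matrix(rnorm(m * n, 0.33, 0.02), m, n)
    avgsd <- matrix(abs(rnorm(m * n, 0.06, 0.03)), m, n)
    hr_missing <- matrix(0L, m, n)

    for (i in seq_len(n)) {
      n_ep <- rpois(1, artifacts$sensor_off_rate * n_days)
      if (n_ep > 0) {
        starts <- sample.int(m, n_ep)
        durs <- round(runif(n_ep, artifacts$sensor_off_duration[1],
                            artifacts$sensor_off_duration[2]))
        for (k in seq_len(n_ep)) {
          idx <- starts[k]:min(m, starts[k] + durs[k] - 1)
          mxyz[idx, i] <- 0
          avgm[idx, i] <- 0
          avgsd[idx, i] <- 0
          hr_obs[idx, i] <- runif(length(idx), 25, 180)
        }
      }
      n_sp <- rpois(1, artifacts$spike_rate * n_days)
      if (n_sp > 0) {
        sp <- sample.int(m, n_sp)
        hr_obs[sp, i] <- hr_obs[sp, i] + artifacts$spike_magnitude
      }
      if (artifacts$missing_minute_rate > 0) {
        miss <- runif(m) < artifacts$missing_minute_rate
        hr_obs[miss, i] <- NA_real_
        hr_missing[miss, i] <- 1L
      }
    }

    minutes <- tibble(
      subject_id = rep(profiles$subject_id, each = m),
      timestamp = rep(times, n),
      hr_bpm = as.numeric(hr_obs),
      mxyz = as.numeric(mxyz),
      avgm = as.numeric(avgm),
      avgsd = as.numeric(avgsd),
      hr_missing = as.integer(hr_missing),
      hr_true = as.numeric(hr_true)
    )
    truth <- list(
      effects = effects,
      beta = beta,
      random_effects = random_effects_tibble(profiles, re),
      seed = as.integer(seed)
    )
    list(minutes = minutes, truth = truth)
  })
}

#' Simulate hourly observations directly (hour-scale noise)
#'
#' Generates the model's unit of analysis — mean HR per subject, hour of
#' day and day-type — straight from the generative model with AR(1) noise
#' at the hour scale. Hourly averaging of minute-scale AR(1) noise is not
#' itself an AR(1) process, so parameter-recovery experiments use this
#' simulator, which matches the fitted model exactly.
#'
#' @inheritParams simulate_minute_streams
#' @return A list with `hourly` (tibble: `subject_id`, `hour_of_day`,
#'   `is_weekend`, `mean_hr`, `n_minutes`, `hr_true`) and `truth` as in
#'   [simulate_minute_streams()].
#' @export
simulate_hourly <- function(profiles,
                            effects = effect_config(),
                            seed = 1L) {
  validate_profiles(profiles)
  stopifnot(inherits(effects, "effect_config"))
  n <- nrow(profiles)
  grid <- crossing(is_weekend = c(FALSE, TRUE), hour_of_day = 0:23)
  t_day <- grid$hour_of_day + 0.5
  w01 <- as.integer(grid$is_weekend)
  m <- nrow(grid)  # 48 rows per subject, ordered day-type then hour
  beta <- true_fixed_effects(effects)
  slope_basis <- cbind(t_day - 12, harmonic_basis(t_day))

  with_seed(stage_seed(seed, 2L), {
    re <- draw_random_effects(profiles, effects)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      df <- tibble(t = t_day, weekend01 = w01,
                   gender01 = rep(as.integer(profiles$gender[i] == "F"), m),
                   age_c = rep(profiles$age[i] - effects$age_ref, m),
                   pss_c = rep(profiles$pss[i] - effects$pss_ref, m))
      X <- build_fixed_matrix(df, final_model_terms())
      sl <- slope_basis %*% t(re$slopes_workday[i, , drop = FALSE]) * (1 - w01) +
        slope_basis %*% t(re$slopes_weekend[i, , drop = FALSE]) * w01
      hr_true <- as.numeric(X %*% beta) + re$b0_subject[i] +
        (1 - w01) * re$b0_workday[i] + w01 * re$b0_weekend[i] +
        as.numeric(sl)
      noise <- c(ar1_noise(24, effects$ar1_rho_hourly, effects$resid_sd_hourly),
                 ar1_noise(24, effects$ar1_rho_hourly, effects$resid_sd_hourly))
      rows[[i]] <- tibble(
        subject_id = profiles$subject_id[i],
        hour_of_day = grid$hour_of_day,
        is_weekend = grid$is_weekend,
        mean_hr = hr_true + noise,
        n_minutes = 60L,
        hr_true = hr_true
      )
    }
    truth <- list(
      effects = effects,
      beta = beta,
      random_effects = random_effects_tibble(profiles, re),
      seed = as.integer(seed)
    )
    list(hourly = bind_rows(rows), truth = truth)
  })
}
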