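test_that("degenerate configuration yields constant heart rate", {
  prof <- tibble::tibble(
    subject_id = c("A", "B"), gender = factor(c("M", "F"), c("M", "F")),
    age = c(39L, 39L), pss = c(14L, 14L))
  # references match the covariates exactly so modulation terms vanish
  eff2 <- effect_config(
    harmonic_amplitudes = c(h24 = 0, h12 = 0, h8 = 0, h6 = 0),
    weekend_harmonic_delta = c(h24 = 0, h12 = 0, h8 = 0, h6 = 0),
    re_sd_intercept_subject = 0, re_sd_intercept_daytype = 0,
    re_sd_slopes = c(hour = 0, h24 = 0, h12 = 0, h8 = 0, h6 = 0),
    resid_sd = 0, age_ref = 39, pss_ref = 14)
  sim <- simulate_minute_streams(prof, eff2, no_artifacts(), seed = 1)
  hr_m <- sim$minutes$hr_bpm[sim$minutes$subject_id == "A"]
  hr_f <- sim$minutes$hr_bpm[sim$minutes$subject_id == "B"]
  expect_equal(unique(hr_m), eff2$baseline_hr)
  expect_equal(unique(hr_f), eff2$baseline_hr + eff2$gender_shift)
})

test_that("higher PSS widens the male circadian range under default signs", {
  mk <- function(pss) tibble::tibble(
    subject_id = "S", gender = factor("M", c("M", "F")),
    age = 39L, pss = as.integer(pss))
  eff <- effect_config(
    re_sd_intercept_subject = 0, re_sd_intercept_daytype = 0,
    re_sd_slopes = c(hour = 0, h24 = 0, h12 = 0, h8 = 0, h6 = 0),
    resid_sd = 0)
  rng <- function(pss) {
    sim <- simulate_minute_streams(mk(pss), eff, no_artifacts(), seed = 3)
    fri <- sim$minutes$hr_true[lubridate::wday(sim$minutes$timestamp,
                                               week_start = 1) == 5]
    diff(range(fri))
  }
  expect_gt(rng(25), rng(5))
})

test_that("minute AR(1) noise has the configured lag-1 autocorrelation", {
  prof <- tiny_cohort(2, 1, seed = 8)
  eff <- effect_config(ar1_rho = 0.8)
  sim <- simulate_minute_streams(prof, eff, no_artifacts(), seed = 8)
  resid <- sim$minutes$hr_bpm - sim$minutes$hr_true
  r1 <- sapply(split(resid, sim$minutes$subject_id), function(e) {
    stats::cor(e[-1], e[-length(e)])
  })
  expect_gt(length(resid), 10000)
  expect_lt(abs(mean(r1) - 0.8), 0.02)
})

test_that("a pure circadian signal concentrates spectral power at 1/24 h", {
  prof <- fixture_profile(age = 39L, pss = 14L)
  eff <- effect_config(
    harmonic_amplitudes = c(h24 = 6, h12 = 0, h8 = 0, h6 = 0),
    weekend_harmonic_delta = c(h24 = 0, h12 = 0, h8 = 0, h6 = 0),
    re_sd_intercept_subject = 0, re_sd_intercept_daytype = 0,
    re_sd_slopes = c(hour = 0, h24 = 0, h12 = 0, h8 = 0, h6 = 0),
    resid_sd = 0, age_ref = 39, pss_ref = 14)
  sim <- simulate_minute_streams(prof, eff, no_artifacts(), seed = 2)
  x <- sim$minutes$hr_true[1:4320]  # exactly 3 days -> 1/24 h is bin k = 3
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2
  k <- which.max(pw[2:(length(x) / 2)])  # index offset: pw[2] is k = 1
  expect_equal(k, 3L)
})

test_that("minute streams are reproducible and cover the recording window", {
  prof <- tiny_cohort(2, 1, seed = 3)
  a <- simulate_minute_streams(prof, effect_config(), artifact_config(),
                               seed = 10)
  b <- simulate_minute_streams(prof, effect_config(), artifact_config(),
                               seed = 10)
  c <- simulate_minute_streams(prof, effect_config(), artifact_config(),
                               seed = 11)
  expect_identical(a$minutes, b$minutes)
  expect_false(identical(a$minutes$hr_bpm, c$minutes$hr_bpm))
  # Thursday 08:00 .. Monday 15:59 = 104 h of minutes per subject
  per_subj <- table(a$minutes$subject_id)
  expect_true(all(per_subj == 104 * 60))
})

test_that("hourly simulator matches the declared fixed-effect truth on average", {
  prof <- generate_cohort(cohort_config(n_subjects = 150, n_female = 65,
                                        seed = 12))
  eff <- effect_config()
  sh <- simulate_hourly(prof, eff, seed = 12)
  expect_equal(nrow(sh$hourly), 150 * 48)
  # noise-free values reconstructed from truth: beta + random effects
  d <- build_design(sh$hourly, prof, centers = c(age = eff$age_ref,
                                                 pss = eff$pss_ref))
  fixed_part <- as.numeric(d$X %*% sh$truth$beta)
  re_part <- sh$hourly$hr_true - fixed_part
  # per-subject mean of the random part should match the drawn intercepts
  # up to the slope terms averaging over hours
  re_tab <- sh$truth$random_effects
  subj_mean <- tapply(re_part, sh$hourly$subject_id, mean)
  expect_lt(max(abs(subj_mean[re_tab$subject_id] - re_tab$b0_subject -
                      (re_tab$b0_workday + re_tab$b0_weekend) / 2 -
                      ((re_tab$workday_hour + re_tab$weekend_hour) / 2) *
                      mean((0:23 + 0.5) - 12))), 1e-8)
})
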