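test_that("window trimming keeps Friday 00:00 through Monday 15:59", {
  ts <- as.POSIXct(c("2016-06-02 23:59:00",   # Thursday night
                     "2016-06-03 00:00:00",   # Friday 00:00
                     "2016-06-06 15:59:00",   # Monday 15:59
                     "2016-06-06 16:00:00"),  # Monday 16:00
                   tz = "UTC")
  minutes <- tibble::tibble(subject_id = "S1", timestamp = ts,
                            hr_bpm = 70, mxyz = 1, avgm = 0.3, avgsd = 0.05,
                            hr_missing = 0L)
  out <- trim_window(minutes)
  expect_equal(format(out$timestamp, "%a %H:%M"),
               c("Fri 00:00", "Mon 15:59"))
})

test_that("a full generator stream trims to exactly 88 x 60 minute slots", {
  prof <- fixture_profile()
  sim <- simulate_minute_streams(prof, effect_config(), no_artifacts(),
                                 seed = 1)
  out <- trim_window(sim$minutes)
  expect_equal(nrow(out), 88 * 60)
})

test_that("subjects with no in-window data are dropped with a logged reason", {
  minutes <- fixture_minutes(c(70, 71),
                             start = as.POSIXct("2016-06-02 09:00:00",
                                                tz = "UTC"))  # Thursday only
  expect_message(out <- trim_window(minutes), "dropped 1 subject")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "exclusions")$subject_id, "S1")
})

test_that("the age-predicted maximum heart rate follows 208 - 0.7 * age", {
  expect_equal(tanaka_max_hr(40), 180)
  expect_equal(tanaka_max_hr(c(20, 60)), c(194, 166))
  expect_gt(tanaka_max_hr(20), tanaka_max_hr(60))
  expect_error(tanaka_max_hr(0), class = "circastress_domain_error")
  expect_error(tanaka_max_hr(-3), class = "circastress_domain_error")
})

test_that("HR filtering applies the band, the floor and the ceiling", {
  # constant series: zero SD band keeps everything
  minutes <- fixture_minutes(rep(70, 50))
  minutes$is_malfunction <- FALSE
  out <- filter_hr(minutes, fixture_profile())
  expect_true(all(out$hr_valid))

  # 500 minutes at 70 +/- 2 with one 200 bpm spike: the spike exceeds
  # median +/- 3 SD (computed on the full malfunction-cleaned series)
  set.seed(7)
  hr <- rnorm(500, 70, 2)
  hr[250] <- 200
  minutes <- fixture_minutes(hr)
  minutes$is_malfunction <- FALSE
  m <- median(hr)
  s <- sd(hr)
  expect_gt(200, m + 3 * s)  # oracle: the spike is outside the band
  out <- filter_hr(minutes, fixture_profile())
  expect_false(out$hr_valid[250])
  expect_true(all(out$hr_valid[-250]))

  # a 25 bpm value inside a wide band is still removed by the 30 bpm floor
  hr <- c(rnorm(200, 70, 20), 25)
  minutes <- fixture_minutes(hr)
  minutes$is_malfunction <- FALSE
  mm <- median(hr); ss <- sd(hr)
  expect_gt(25, mm - 3 * ss)
  out <- filter_hr(minutes, fixture_profile())
  expect_false(out$hr_valid[201])

  # values above the age-predicted ceiling are removed
  hr <- c(rnorm(300, 120, 30), 170)
  minutes <- fixture_minutes(hr)
  minutes$is_malfunction <- FALSE
  out <- filter_hr(minutes, fixture_profile(age = 60L))  # ceiling 166
  expect_false(out$hr_valid[301])
})

test_that("filtering is idempotent", {
  set.seed(3)
  minutes <- fixture_minutes(c(rnorm(300, 70, 3), 200, 25))
  minutes$is_malfunction <- FALSE
  once <- filter_hr(minutes, fixture_profile())
  twice <- filter_hr(once, fixture_profile())
  expect_identical(once$hr_valid, twice$hr_valid)
})

test_that("the band-then-floor order is fixed and differs from floor-then-band", {
  hr <- c(rep(70, 100), rep(20, 5), 40)
  minutes <- fixture_minutes(hr)
  minutes$is_malfunction <- FALSE
  out <- filter_hr(minutes, fixture_profile())
  # with the band computed on all clean minutes the 20s inflate the SD, so
  # 40 stays; flooring first would shrink the band to ~[70, 70] and drop 40
  expect_true(out$hr_valid[106])
  expect_true(all(!out$hr_valid[101:105]))
  floor_first <- hr[hr >= 30]
  band <- median(floor_first) + c(-3, 3) * sd(floor_first)
  expect_lt(40, band[1])  # oracle for the counterfactual order
})

test_that("hourly aggregation pools by hour of day and day-type", {
  # two Friday hours and one Saturday hour for one subject, plus a second
  # subject, with hand-computable means
  fri <- as.POSIXct("2016-06-03 03:00:00", tz = "UTC")
  sat <- as.POSIXct("2016-06-04 03:00:00", tz = "UTC")
  mk <- function(id, start, hrs) {
    m <- fixture_minutes(hrs, subject_id = id, start = start)
    m$is_malfunction <- FALSE
    m$hr_valid <- TRUE
    m
  }
  minutes <- dplyr::bind_rows(
    mk("A", fri, c(60, 62)), mk("A", sat, c(80, 84, 88)),
    mk("B", fri, c(100, 90)))
  cfg <- filter_config(min_valid_minutes_per_hour = 1)
  out <- aggregate_hourly(minutes, cfg)
  expect_equal(nrow(out), 2 * 48)
  a_wk <- out$mean_hr[out$subject_id == "A" & out$hour_of_day == 3 &
                        !out$is_weekend]
  a_we <- out$mean_hr[out$subject_id == "A" & out$hour_of_day == 3 &
                        out$is_weekend]
  b_wk <- out$mean_hr[out$subject_id == "B" & out$hour_of_day == 3 &
                        !out$is_weekend]
  expect_equal(a_wk, mean(c(60, 62)))
  expect_equal(a_we, mean(c(80, 84, 88)))
  expect_equal(b_wk, mean(c(100, 90)))
  # weekend row exists but is missing for B
  expect_true(is.na(out$mean_hr[out$subject_id == "B" & out$hour_of_day == 3 &
                                  out$is_weekend]))
  # aggregation conserves valid minutes
  expect_equal(sum(out$n_minutes), sum(minutes$hr_valid))
})

test_that("hour cells below the minute threshold are emitted as missing", {
  fri <- as.POSIXct("2016-06-03 10:00:00", tz = "UTC")
  minutes <- fixture_minutes(rep(70, 20), start = fri)
  minutes$hr_valid <- TRUE
  out <- aggregate_hourly(minutes, filter_config(min_valid_minutes_per_hour = 30))
  cell <- out[out$hour_of_day == 10 & !out$is_weekend, ]
  expect_true(is.na(cell$mean_hr))
  expect_equal(cell$n_minutes, 20L)
})

test_that("inclusion requires 24 valid hour-slots in both day-types", {
  mk_hours <- function(id, day_starts, hours_per_day) {
    rows <- list()
    for (i in seq_along(day_starts)) {
      for (h in seq_len(hours_per_day[i]) - 1) {
        m <- fixture_minutes(rep(70, 60), subject_id = id,
                             start = day_starts[i] + h * 3600)
        rows[[length(rows) + 1]] <- m
      }
    }
    out <- dplyr::bind_rows(rows)
    out$hr_valid <- TRUE
    out
  }
  fri <- as.POSIXct("2016-06-03 00:00:00", tz = "UTC")
  sat <- fri + 86400; sun <- fri + 2 * 86400; mon <- fri + 3 * 86400
  # A: weekend only; B: 30 workday / 23 weekend hours; C: fully compliant
  minutes <- dplyr::bind_rows(
    mk_hours("A", c(sat, sun), c(24, 24)),
    mk_hours("B", c(fri, mon, sat), c(24, 6, 23)),
    mk_hours("C", c(fri, sat, sun, mon), c(24, 24, 24, 16)))
  cfg <- filter_config()
  hourly <- aggregate_hourly(minutes, cfg)
  out <- apply_inclusion(hourly, minutes, cfg)
  expect_setequal(unique(out$subject_id), "C")
  excl <- attr(out, "exclusions")
  expect_setequal(excl$subject_id, c("A", "B"))
})

test_that("artifact-free generator output loses essentially nothing to the filters", {
  prof <- tiny_cohort(6, 3, seed = 5)
  sim <- simulate_minute_streams(prof, effect_config(), no_artifacts(),
                                 seed = 5)
  prep <- preprocess_minutes(sim$minutes, prof)
  # an exact zero is unattainable under unbounded Gaussian noise (the
  # median +/- 3SD band has positive tail mass); essentially nothing means
  # well under 0.2% of minutes
  removed <- mean(!prep$minutes$hr_valid)
  expect_lte(removed, 2e-3)
  expect_equal(nrow(prep$hourly), 6 * 48)
  expect_equal(sum(is.na(prep$hourly$mean_hr)), 0)
})
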