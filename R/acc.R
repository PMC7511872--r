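## Accelerometer features and the technical-malfunction indicator.
##
## Three per-minute features are computed from raw 32 Hz triplets: MXYZ (the
## mean sample magnitude), AVGM (mean of the three per-axis means) and AVGSD
## (mean of the three per-axis population SDs). When the patch is off-body
## or saturated these features stop fluctuating, so summed absolute
## first-differences of the features over the 10 closest minutes fall below
## a small threshold (5e-4); such minutes are flagged as malfunction and
## excluded from analysis.

#' Per-minute accelerometer features from raw 32 Hz samples
#'
#' @param samples Data frame with columns `x`, `y`, `z`: the raw
#'   accelerometer triplets of one minute (any number of samples >= 1).
#' @return A one-row tibble with `mxyz` (mean magnitude, g), `avgm` (mean of
#'   per-axis means, g) and `avgsd` (mean of per-axis population SDs, g).
#'   An empty minute yields an all-`NA` row (a missing-feature marker, not
#'   zero).
#' @export
#' @examples
#' compute_minute_features(data.frame(x = 0, y = 0, z = 1))
compute_minute_features <- function(samples) {
  if (nrow(samples) == 0) {
    return(tibble(mxyz = NA_real_, avgm = NA_real_, avgsd = NA_real_))
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  tibble(
    mxyz = mean(sqrt(samples$x^2 + samples$y^2 + samples$z^2)),
    avgm = mean(c(mean(samples$x), mean(samples$y), mean(samples$z))),
    avgsd = mean(c(pop_sd(samples$x), pop_sd(samples$y), pop_sd(samples$z)))
  )
}

#' Per-minute features for a raw accelerometer table
#'
#' Applies [compute_minute_features()] to every subject-by-minute group of a
#' long 32 Hz table (`subject_id`, `timestamp`, `x`, `y`, `z`).
#'
#' @param acc Raw accelerometer tibble.
#' @return Tibble with one row per subject and minute.
#' @export
acc_features_by_minute <- function(acc) {
  acc |>
    mutate(timestamp = as.POSIXct(trunc(timestamp, "mins"))) |>
    group_by(subject_id, timestamp) |>
    summarise(compute_minute_features(data.frame(x = x, y = y, z = z)),
              .groups = "drop")
}

## Windowed sum of absolute first differences for one feature series.
## For minute t the window is the 11 closest available minutes (centred on t,
## shifted inwards at the series edges), giving 10 first differences.
window_diff_sum <- function(v) {
  L <- length(v)
  if (L < 2) return(rep(NA_real_, L))
  d <- abs(diff(v))
  nd <- length(d)
  win <- min(10L, nd)
  cd <- c(0, cumsum(d))
  lo <- pmin(pmax(seq_len(L) - 5L, 1L), nd - win + 1L)
  cd[lo + win] - cd[lo]
}

#' Technical-malfunction indicator for minute feature series
#'
#' For every minute, sums the absolute first differences of the three
#' accelerometer features (`mxyz`, `avgm`, `avgsd`) over the 10 closest
#' minutes (a centred 11-minute window, shifted inwards at the series
#' edges). A minute is flagged as malfunction when the indicator is
#' strictly below the threshold `5e-4` — a frozen signal has (near-)zero
#' differences. Minutes whose indicator cannot be computed (fewer than two
#' minutes available, or missing features in the window) are flagged
#' `NA` and treated as malfunction downstream (conservative exclusion).
#'
#' @param minutes Tibble with `subject_id`, `timestamp`, `mxyz`, `avgm`,
#'   `avgsd` (minute-indexed, ordered or orderable by timestamp).
#' @param threshold Malfunction threshold (strict `<` comparison).
#' @return The input with `indicator` and `is_malfunction` columns added.
#' @export
flag_malfunction <- function(minutes, threshold = acc_malfunction_threshold) {
  minutes |>
    arrange(subject_id, timestamp) |>
    group_by(subject_id) |>
    mutate(indicator = window_diff_sum(mxyz) + window_diff_sum(avgm) +
             window_diff_sum(avgsd)) |>
    ungroup() |>
    mutate(is_malfunction = indicator < threshold)
}

#' Malfunction flag for a single minute of a feature series
#'
#' Scalar form of [flag_malfunction()]: evaluates the indicator at one
#' minute index of a feature series.
#'
#' @param features Tibble with columns `mxyz`, `avgm`, `avgsd`, one row per
#'   consecutive minute.
#' @param t Minute index (row number) to evaluate.
#' @param threshold Malfunction threshold.
#' @return A one-row tibble with `indicator` and `is_malfunction`.
#' @export
malfunction_indicator <- function(features, t,
                                  threshold = acc_malfunction_threshold) {
  stopifnot(t >= 1, t <= nrow(features))
  ind <- (window_diff_sum(features$mxyz) + window_diff_sum(features$avgm) +
            window_diff_sum(features$avgsd))[t]
  tibble(indicator = ind, is_malfunction = ind < threshold)
}
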