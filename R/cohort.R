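#' Generate a synthetic cohort of subject profiles
#'
#' Draws a cohort of subjects (id, gender, age, PSS-10 score) from the
#' distributions in a [cohort_config()]. Ages are normal draws rounded to
#' integers and clipped to the configured range; PSS scores are normal draws
#' redrawn until they land in \[0, 40\] (so no probability mass piles up at
#' the bounds) and then rounded. The female PSS stratum is shifted
#' `pss_female_shift` points above the male stratum while preserving the
#' cohort-level mean.
#'
#' Deterministic: the same config (including its seed) always produces the
#' same cohort.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `subject_id` (character), `gender`
#'   (factor, levels `M`/`F`), `age` (integer years) and `pss` (integer).
#' @export
#' @examples
#' generate_cohort(cohort_config(n_subjects = 5, n_female = 2, seed = 7))
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  nf <- config$n_female
  prop_f <- nf / n
  pss_mean_m <- config$pss_mean - config$pss_female_shift * prop_f
  pss_mean_f <- pss_mean_m + config$pss_female_shift
  with_seed(config$seed, {
    gender <- factor(rep(c("F", "M"), c(nf, n - nf)), levels = c("M", "F"))
    age <- as.integer(pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)),
                                config$age_range[1]), config$age_range[2]))
    mu <- if_else(gender == "F", pss_mean_f, pss_mean_m)
    pss <- rnorm(n, mu, config$pss_sd)
    bad <- which(pss < 0 | pss > 40)
    while (length(bad) > 0) {
      pss[bad] <- rnorm(length(bad), mu[bad], config$pss_sd)
      bad <- bad[pss[bad] < 0 | pss[bad] > 40]
    }
    tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      gender = gender,
      age = age,
      pss = as.integer(round(pss))
    )
  })
}

validate_profiles <- function(profiles) {
  need <- c("subject_id", "gender", "age", "pss")
  if (!all(need %in% names(profiles))) {
    abort(sprintf("`profiles` must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "circastress_config_error")
  }
  if (anyDuplicated(profiles$subject_id)) {
    abort("`subject_id` must be unique within a cohort.",
          class = "circastress_config_error")
  }
  if (any(profiles$age <= 0)) {
    abort("Ages must be positive.", class = "circastress_config_error")
  }
  if (any(profiles$pss < 0 | profiles$pss > 40)) {
    abort("PSS scores must lie in [0, 40].",
          class = "circastress_config_error")
  }
  invisible(profiles)
}
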