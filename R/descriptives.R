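## Descriptive statistics: median/IQR population table and the two
## nonparametric comparisons (gender strata: Mann-Whitney-Wilcoxon;
## workday vs weekend: Wilcoxon signed rank). Quartiles use linear
## interpolation (type 7, the R default) so IQR values are reproducible
## bit-for-bit.

subject_hr_medians <- function(hourly) {
  hourly |>
    filter(!is.na(mean_hr)) |>
    group_by(subject_id) |>
    summarise(
      hr_median = median(mean_hr),
      hr_workday = median(mean_hr[!is_weekend]),
      hr_weekend = median(mean_hr[is_weekend]),
      .groups = "drop"
    )
}

#' Population characteristics table (median / IQR by stratum)
#'
#' Summarizes age, PSS score and heart rate by cohort stratum. Heart rate
#' is first reduced per subject to the median of that subject's hourly
#' means (within day-type for the workday/weekend strata), then the cohort
#' median and IQR of these per-subject values are reported. Age and PSS are
#' summarized directly. Empty strata are omitted.
#'
#' @param subjects Subject profile tibble.
#' @param hourly Hourly observation table.
#' @return Tibble: `variable`, `stratum`, `n`, `median`, `iqr`.
#' @export
summarize_cohort <- function(subjects, hourly) {
  validate_profiles(subjects)
  hr <- subjects |>
    inner_join(subject_hr_medians(hourly), by = "subject_id")
  srow <- function(variable, stratum, v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      inform(sprintf("summarize_cohort: empty stratum %s / %s omitted.",
                     variable, stratum))
      return(NULL)
    }
    tibble(variable = variable, stratum = stratum, n = length(v),
           median = median(v), iqr = IQR(v))
  }
  bind_rows(
    srow("age", "male", subjects$age[subjects$gender == "M"]),
    srow("age", "female", subjects$age[subjects$gender == "F"]),
    srow("age", "total", subjects$age),
    srow("pss", "male", subjects$pss[subjects$gender == "M"]),
    srow("pss", "female", subjects$pss[subjects$gender == "F"]),
    srow("pss", "total", subjects$pss),
    srow("hr", "male", hr$hr_median[hr$gender == "M"]),
    srow("hr", "female", hr$hr_median[hr$gender == "F"]),
    srow("hr", "workdays", hr$hr_workday),
    srow("hr", "weekend", hr$hr_weekend),
    srow("hr", "total", hr$hr_median)
  )
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sample rank test; the reported `statistic` is the rank-sum-based W
#' (U) statistic of `x`, computed with average ranks for ties. P values are
#' exact for small tie-free samples and use the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return One-row tibble: `method`, `statistic`, `p.value`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.",
          class = "circastress_contract_error")
  }
  ht <- suppressWarnings(wilcox.test(x, y, alternative = alternative))
  tibble(method = "mann-whitney", statistic = unname(ht$statistic),
         p.value = ht$p.value, n_x = length(x), n_y = length(y))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired rank test; `statistic` is V, the sum of positive signed ranks over
#' the nonzero differences. Exact p for small tie-free samples, normal
#' approximation with continuity correction otherwise. If every difference
#' is zero the result is degenerate: a warning is raised and the p value is
#' `NA`.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return One-row tibble: `method`, `statistic`, `p.value`, `n`.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y) || length(x) == 0) {
    abort("`x` and `y` must be non-empty and of equal length.",
          class = "circastress_contract_error")
  }
  d <- x - y
  if (all(d == 0)) {
    warn("All paired differences are zero; signed-rank test is degenerate.")
    return(tibble(method = "wilcoxon-signed-rank", statistic = 0,
                  p.value = NA_real_, n = length(x)))
  }
  ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                     alternative = alternative))
  tibble(method = "wilcoxon-signed-rank", statistic = unname(ht$statistic),
         p.value = ht$p.value, n = length(x))
}

#' Nonparametric group comparisons for the population table
#'
#' Runs the three male-vs-female Mann-Whitney tests (age, PSS, per-subject
#' median HR) and the paired workday-vs-weekend signed-rank test on
#' per-subject day-type HR medians.
#'
#' @param subjects Subject profiles.
#' @param hourly Hourly observation table.
#' @param hr_reduction `"subject_median"` (default) compares per-subject
#'   median HR between genders; `"hourly"` compares all hourly values.
#' @return Tibble with one row per test.
#' @export
compare_groups <- function(subjects, hourly,
                           hr_reduction = c("subject_median", "hourly")) {
  hr_reduction <- match.arg(hr_reduction)
  hr <- subjects |> inner_join(subject_hr_medians(hourly), by = "subject_id")
  m <- hr$gender == "M"
  hr_vals <- if (hr_reduction == "subject_median") {
    list(x = hr$hr_median[m], y = hr$hr_median[!m])
  } else {
    hh <- hourly |> filter(!is.na(mean_hr)) |>
      inner_join(select(subjects, subject_id, gender), by = "subject_id")
    list(x = hh$mean_hr[hh$gender == "M"], y = hh$mean_hr[hh$gender == "F"])
  }
  paired <- filter(hr, !is.na(hr_workday) & !is.na(hr_weekend))
  bind_rows(
    mutate(mann_whitney(hr$age[m], hr$age[!m]), variable = "age"),
    mutate(mann_whitney(hr$pss[m], hr$pss[!m]), variable = "pss"),
    mutate(mann_whitney(hr_vals$x, hr_vals$y), variable = "hr"),
    mutate(wilcoxon_signed_rank(paired$hr_workday, paired$hr_weekend),
           variable = "hr_daytype")
  ) |>
    select(variable, method, statistic, p.value, everything())
}
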