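## Plain-text serialization of cohorts: subjects.csv, minutes.csv,
## truth.json. Timestamps are written as ISO-8601 local clock time (the
## package works in a single fixed UTC-offset frame; see the vignette).

fmt_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write a simulated cohort to disk
#'
#' Writes `subjects.csv` (`subject_id,gender,age,pss`, gender coded `M`/`F`),
#' `minutes.csv` (`subject_id,timestamp,hr_bpm,mxyz,avgm,avgsd,hr_missing`)
#' and, when ground truth is supplied, `truth.json` (the effect
#' configuration and the realized per-subject random effects). The
#' noise-free `hr_true` column is simulator metadata, not wearable output,
#' and is not part of the minutes.csv schema.
#'
#' @param streams Result of [simulate_minute_streams()], or a minutes
#'   tibble.
#' @param profiles Subject profile tibble.
#' @param path Directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(streams, profiles, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  minutes <- if (is.data.frame(streams)) streams else streams$minutes
  truth <- if (is.data.frame(streams)) NULL else streams$truth
  write_csv(profiles, file.path(path, "subjects.csv"))
  out <- minutes |>
    mutate(timestamp = fmt_ts(timestamp)) |>
    select(subject_id, timestamp, hr_bpm, mxyz, avgm, avgsd, hr_missing)
  write_csv(out, file.path(path, "minutes.csv"))
  if (!is.null(truth)) {
    tr <- list(
      effects = unclass(truth$effects),
      beta = as.list(truth$beta),
      random_effects = truth$random_effects,
      seed = truth$seed
    )
    write_json(tr, file.path(path, "truth.json"),
               auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Parses and validates `subjects.csv` and `minutes.csv`. Malformed fields
#' raise a parse error naming the offending line and column; timestamps
#' must be strictly increasing within each subject.
#'
#' @param path Directory containing the files.
#' @return A list with `minutes` and `profiles` tibbles (and `truth` when
#'   `truth.json` is present).
#' @export
read_cohort <- function(path) {
  sub_file <- file.path(path, "subjects.csv")
  min_file <- file.path(path, "minutes.csv")
  for (f in c(sub_file, min_file)) {
    if (!file.exists(f)) {
      abort(sprintf("Missing cohort file `%s`.", f),
            class = "circastress_parse_error")
    }
  }
  profiles <- read_csv(sub_file, col_types = cols(
    subject_id = col_character(), gender = col_character(),
    age = col_integer(), pss = col_integer()
  ), progress = FALSE)
  stop_on_problems(profiles, sub_file)
  if (!all(profiles$gender %in% c("M", "F"))) {
    abort(sprintf("`%s`: gender must be M or F.", sub_file),
          class = "circastress_parse_error")
  }
  profiles$gender <- factor(profiles$gender, levels = c("M", "F"))

  minutes <- read_csv(min_file, col_types = cols(
    subject_id = col_character(), timestamp = col_character(),
    hr_bpm = col_double(), mxyz = col_double(), avgm = col_double(),
    avgsd = col_double(), hr_missing = col_integer()
  ), progress = FALSE)
  stop_on_problems(minutes, min_file)
  ts <- parse_ts(minutes$timestamp)
  bad <- which(is.na(ts) & !is.na(minutes$timestamp))
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s`: unparseable timestamp at line %d, column `timestamp`.",
      min_file, bad[1] + 1L), class = "circastress_parse_error")
  }
  minutes$timestamp <- ts
  if (nrow(minutes) > 1) {
    same_subj <- minutes$subject_id == lag(minutes$subject_id)
    nonmono <- which(same_subj & ts <= lag(ts))
    if (length(nonmono) > 0) {
      abort(sprintf(
        "`%s`: non-monotone timestamp for subject %s at line %d, column `timestamp`.",
        min_file, minutes$subject_id[nonmono[1]], nonmono[1] + 1L),
        class = "circastress_parse_error")
    }
  }
  out <- list(minutes = minutes, profiles = profiles)
  truth_file <- file.path(path, "truth.json")
  if (file.exists(truth_file)) out$truth <- read_json(truth_file)
  out
}

stop_on_problems <- function(tbl, file) {
  pr <- problems(tbl)
  if (nrow(pr) > 0) {
    abort(sprintf("`%s`: parse error at line %d, column %s (expected %s).",
                  file, pr$row[1], pr$col[1], pr$expected[1]),
          class = "circastress_parse_error")
  }
  invisible(tbl)
}
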