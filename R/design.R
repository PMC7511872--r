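## Design construction for the harmonic mixed-effects model.
##
## A built design carries the fixed-effect matrix X (columns in term order),
## the response, and the random-effect structure: per subject, a random
## intercept; per subject-by-day-type series, a random intercept and
## (optionally) random slopes for the centred hour and each sin/cos pair,
## with day-type-specific variances. Residuals are AR(1) across the hour
## order within each series. For speed, subjects sharing the same
## (day-type, hour) row pattern are grouped: their marginal covariance is
## identical for any parameter value, so one Cholesky factor per group
## serves every subject in it.

#' AR(1) correlation matrix
#'
#' Entry (j, k) equals `rho^|j-k|`: first-order autoregressive correlation
#' across an ordered series.
#'
#' @param n Series length.
#' @param rho Autocorrelation, `|rho| < 1`.
#' @return An `n` x `n` correlation matrix.
#' @export
#' @examples
#' ar1_matrix(4, 0.5)
ar1_matrix <- function(n, rho) {
  if (!is.finite(rho) || abs(rho) >= 1) {
    abort("`rho` must satisfy |rho| < 1.",
          class = "circastress_domain_error")
  }
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

ar1_block <- function(lens, rho) {
  m <- sum(lens)
  R <- matrix(0, m, m)
  at <- 0L
  for (l in lens) {
    R[at + seq_len(l), at + seq_len(l)] <- ar1_matrix(l, rho)
    at <- at + l
  }
  R
}

## Random-effect design for one subject pattern (daytype / t vectors).
## Returns Z (m x q) and varmap (variance-parameter index per column).
## Variance parameters: 1 subject intercept, 2 day-type intercept, then for
## each day-type (workday, weekend) x slope term (hour, h24, h12, h8, h6)
## in order.
random_structure <- function(daytype, t_hours, random = c("final", "reduced", "none")) {
  random <- match.arg(random)
  m <- length(daytype)
  if (random == "none") {
    return(list(Z = matrix(0, m, 0), varmap = integer(0), k_v = 0L,
                var_names = character(0)))
  }
  Z <- cbind(1, 1 - daytype, daytype)
  varmap <- c(1L, 2L, 2L)
  nms <- c("intercept_subject", "intercept_daytype")
  if (random == "final") {
    slope_cols <- cbind(hour = t_hours - 12, harmonic_basis(t_hours))
    slope_terms <- list(hour = 1L, h24 = 2:3, h12 = 4:5, h8 = 6:7, h6 = 8:9)
    vi <- 2L
    for (d in 0:1) {
      ind <- if (d == 0) 1 - daytype else daytype
      for (tn in names(slope_terms)) {
        vi <- vi + 1L
        cols <- slope_cols[, slope_terms[[tn]], drop = FALSE] * ind
        Z <- cbind(Z, cols)
        varmap <- c(varmap, rep(vi, ncol(cols)))
        nms <- c(nms, sprintf("slope_%s_%s", tn,
                              if (d == 0) "workday" else "weekend"))
      }
    }
  }
  list(Z = Z, varmap = varmap, k_v = max(varmap), var_names = nms)
}

#' Build the design for the harmonic mixed-effects model
#'
#' Joins hourly observations with subject covariates and constructs the
#' fixed-effect matrix (columns in term order; harmonics evaluated at the
#' hour-bin centre `hour_of_day + 0.5`; gender coded 0 = male, 1 = female;
#' weekend coded 0/1; age and PSS mean-centred), the grouping structure, and
#' the random-effect design. Rows with missing `mean_hr` are excluded.
#'
#' @param hourly Hourly observation tibble ([aggregate_hourly()] /
#'   [simulate_hourly()]).
#' @param subjects Subject profile tibble.
#' @param terms Fixed-effect term labels (default the final model).
#' @param random Random-effect structure: `"final"` (intercepts + day-type
#'   specific hour/harmonic slopes), `"reduced"` (intercepts only) or
#'   `"none"`.
#' @param ar1 Model residuals as AR(1) within each subject-by-day-type
#'   series (`TRUE`) or independent (`FALSE`).
#' @param centers Optional named vector `c(age = ..., pss = ...)` of
#'   centring constants; defaults to the means over included subjects.
#' @return An object of class `harmonic_design`.
#' @export
build_design <- function(hourly, subjects,
                         terms = final_model_terms(),
                         random = c("final", "reduced", "none"),
                         ar1 = TRUE,
                         centers = NULL) {
  random <- match.arg(random)
  validate_profiles(subjects)
  validate_term_hierarchy(terms)
  unknown <- setdiff(unique(hourly$subject_id), subjects$subject_id)
  if (length(unknown) > 0) {
    abort(sprintf("Hourly table references unknown subject(s): %s.",
                  paste(head(unknown, 3), collapse = ", ")),
          class = "circastress_spec_error")
  }
  dat <- hourly |>
    filter(!is.na(mean_hr)) |>
    inner_join(select(subjects, subject_id, gender, age, pss),
               by = "subject_id") |>
    arrange(subject_id, is_weekend, hour_of_day)
  if (nrow(dat) == 0) {
    abort("No non-missing hourly observations.",
          class = "circastress_spec_error")
  }
  if (is.null(centers)) {
    subj <- distinct(dat, subject_id, age, pss)
    centers <- c(age = mean(subj$age), pss = mean(subj$pss))
  }
  df <- tibble(
    t = dat$hour_of_day + 0.5,
    weekend01 = as.integer(dat$is_weekend),
    gender01 = as.integer(dat$gender == "F"),
    age_c = dat$age - centers[["age"]],
    pss_c = dat$pss - centers[["pss"]]
  )
  X <- build_fixed_matrix(df, terms)
  y <- dat$mean_hr

  ## Group subjects by identical (day-type, hour) pattern.
  idx_by_subj <- split(seq_len(nrow(dat)), dat$subject_id)
  pattern <- vapply(idx_by_subj, function(ix) {
    paste(df$weekend01[ix], dat$hour_of_day[ix], collapse = ";")
  }, character(1))
  ## Every fixed column factorizes as (time-pattern column) x (subject
  ## scalar): subjects sharing a row pattern share the time part B, so the
  ## GLS cross-products reduce to Hadamard products of B'W^-1 B with the
  ## subject-scalar Gram matrix. Precompute both parts per group.
  subj_scalars <- function(subj_rows) {
    unlist(lapply(terms, function(term) {
      f <- term_factors(term)
      s <- 1
      if ("gender" %in% f) s <- s * df$gender01[subj_rows[1]]
      if ("age" %in% f) s <- s * df$age_c[subj_rows[1]]
      if ("pss" %in% f) s <- s * df$pss_c[subj_rows[1]]
      rep(s, if (any(is_harmonic_factor(f))) 2L else 1L)
    }))
  }
  groups <- lapply(split(names(idx_by_subj), pattern), function(subj_ids) {
    ix1 <- idx_by_subj[[subj_ids[1]]]
    m <- length(ix1)
    rs <- random_structure(df$weekend01[ix1], df$t[ix1], random)
    series_len <- as.integer(table(factor(df$weekend01[ix1], levels = 0:1)))
    series_len <- series_len[series_len > 0]
    rows <- unlist(idx_by_subj[subj_ids], use.names = FALSE)
    n_g <- length(subj_ids)
    Xtall <- X[rows, , drop = FALSE]
    base_df <- tibble(t = df$t[ix1], weekend01 = df$weekend01[ix1],
                      gender01 = 1, age_c = 1, pss_c = 1)
    Bmat <- build_fixed_matrix(base_df, terms)
    Smat <- do.call(rbind, lapply(idx_by_subj[subj_ids], subj_scalars))
    list(
      subjects = subj_ids, m = m, n_g = n_g, rows = rows,
      Z = rs$Z, varmap = rs$varmap, series_len = series_len,
      Xflat = matrix(Xtall, nrow = m),
      yflat = matrix(y[rows], nrow = m),
      Bmat = Bmat, Smat = Smat, SS = crossprod(Smat), tSmat = t(Smat)
    )
  })
  rs_meta <- random_structure(c(0, 1), c(0.5, 0.5), random)
  structure(list(
    X = X, y = y, terms = terms, colnames = colnames(X), p = ncol(X),
    data = dat, centers = centers, random = random, ar1 = ar1,
    k_v = rs_meta$k_v, var_names = rs_meta$var_names,
    groups = groups, n_obs = nrow(dat),
    n_subjects = length(idx_by_subj)
  ), class = "harmonic_design")
}

## Restrict a built design to a subset of fixed-effect columns (used when a
## degenerate cohort leaves columns aliased). `keep` is a sorted index set.
drop_design_columns <- function(design, keep) {
  design$X <- design$X[, keep, drop = FALSE]
  design$colnames <- design$colnames[keep]
  design$p <- length(keep)
  design$groups <- lapply(design$groups, function(g) {
    block <- function(j) (j - 1L) * g$n_g + seq_len(g$n_g)
    g$Xflat <- g$Xflat[, unlist(lapply(keep, block)), drop = FALSE]
    g$Bmat <- g$Bmat[, keep, drop = FALSE]
    g$Smat <- g$Smat[, keep, drop = FALSE]
    g$SS <- crossprod(g$Smat)
    g$tSmat <- t(g$Smat)
    g
  })
  design
}

#' @export
print.harmonic_design <- function(x, ...) {
  cat(sprintf(
    "<harmonic_design> %d obs, %d subjects, %d fixed columns, random = %s, AR(1) = %s\n",
    x$n_obs, x$n_subjects, x$p, x$random, x$ar1))
  invisible(x)
}
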