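# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: rank tests by exhaustive enumeration,
# the mixed-model likelihood by dense joint-covariance evaluation.

# Exact Mann-Whitney U by enumerating all choose(m+n, m) group assignments
# of the pooled ranks. Returns the U statistic of `x` and the exact p value
# (two-sided: doubled smaller tail, capped at 1).
enum_mann_whitney <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  pooled <- r
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(ix) sum(pooled[ix]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  p <- switch(alternative,
    less = p_le,
    greater = p_ge,
    two.sided = min(1, 2 * min(p_le, p_ge)))
  list(statistic = u_obs, p.value = p)
}

# Exact Wilcoxon signed-rank V by enumerating all 2^n sign assignments of
# the ranked absolute differences.
enum_signed_rank <- function(x, y, alternative = "two.sided") {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  p <- switch(alternative,
    less = p_le,
    greater = p_ge,
    two.sided = min(1, 2 * min(p_le, p_ge)))
  list(statistic = v_obs, p.value = p)
}

# Dense multivariate-normal log-likelihood: assembles the full joint
# covariance of every observation (block diagonal over subjects) directly
# from the design's data slot and evaluates the Gaussian log-density with
# determinant() and solve(). Shares no code with harmonic_loglik().
dense_loglik <- function(design, beta, re_var, rho, sigma2) {
  dat <- design$data
  ll <- 0
  for (sid in unique(dat$subject_id)) {
    ix <- which(dat$subject_id == sid)
    m <- length(ix)
    w <- as.integer(dat$is_weekend[ix])
    t_hours <- dat$hour_of_day[ix] + 0.5
    V <- matrix(0, m, m)
    if (design$random != "none") {
      # intercept_subject everywhere; intercept_daytype only within the
      # same day-type series
      V <- re_var[1] + re_var[2] * outer(w, w, "==")
      if (design$random == "final") {
        slope_cols <- cbind(t_hours - 12,
                            sapply(c(24, 12, 8, 6), function(p) sin(2 * pi * t_hours / p)),
                            sapply(c(24, 12, 8, 6), function(p) cos(2 * pi * t_hours / p)))
        # column order: hour, sin24..sin6, cos24..cos6 -> variance lookup
        vmap <- c("hour", paste0("h", c(24, 12, 8, 6)), paste0("h", c(24, 12, 8, 6)))
        for (d in 0:1) {
          ind <- as.numeric(w == d)
          dlab <- if (d == 0) "workday" else "weekend"
          for (j in seq_along(vmap)) {
            v <- re_var[paste0("slope_", vmap[j], "_", dlab)]
            zc <- slope_cols[, j] * ind
            V <- V + v * outer(zc, zc)
          }
        }
      }
    }
    # AR(1) by position within each day-type series
    pos <- stats::ave(seq_along(ix), w, FUN = seq_along)
    R <- (rho^abs(outer(pos, pos, "-"))) * outer(w, w, "==")
    V <- V + sigma2 * R
    r <- design$y[ix] - as.numeric(design$X[ix, , drop = FALSE] %*% beta)
    ll <- ll - 0.5 * (m * log(2 * pi) +
                        as.numeric(determinant(V)$modulus) +
                        as.numeric(t(r) %*% solve(V) %*% r))
  }
  ll
}

# Small deterministic cohort for unit tests.
tiny_cohort <- function(n = 6, n_female = 3, seed = 42) {
  generate_cohort(cohort_config(n_subjects = n, n_female = n_female,
                                seed = seed))
}

# Minute tibble builder for preprocessing fixtures: consecutive minutes for
# one subject starting Friday 00:00, with wear-like ACC features.
fixture_minutes <- function(hr, subject_id = "S1",
                            start = as.POSIXct("2016-06-03 00:00:00", tz = "UTC"),
                            mxyz = NULL) {
  n <- length(hr)
  if (is.null(mxyz)) mxyz <- 1 + 0.01 * (seq_len(n) %% 2)
  tibble::tibble(
    subject_id = subject_id,
    timestamp = start + 60 * (seq_len(n) - 1),
    hr_bpm = hr,
    mxyz = mxyz,
    avgm = 0.33 + 0.01 * (seq_len(n) %% 2),
    avgsd = 0.05 + 0.01 * (seq_len(n) %% 3),
    hr_missing = ifelse(is.na(hr), 1L, 0L)
  )
}

fixture_profile <- function(subject_id = "S1", gender = "M", age = 40L,
                            pss = 14L) {
  tibble::tibble(subject_id = subject_id,
                 gender = factor(gender, levels = c("M", "F")),
                 age = as.integer(age), pss = as.integer(pss))
}
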