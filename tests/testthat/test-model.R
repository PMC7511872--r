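test_that("design columns follow the cosinor parameterization", {
  prof <- fixture_profile()
  hourly <- tidyr::crossing(subject_id = "S1", hour_of_day = 0:23,
                            is_weekend = c(FALSE, TRUE))
  hourly$mean_hr <- 70
  hourly$n_minutes <- 60L
  d <- build_design(hourly, prof, random = "reduced")
  # harmonics are evaluated at the bin centre hour_of_day + 0.5
  row5 <- which(d$data$hour_of_day == 5 & !d$data$is_weekend)[1]
  expect_equal(unname(d$X[row5, "sin24"]), sin(2 * pi * 5.5 / 24))
  # a bin centre of exactly 6.0 h (a quarter period) gives (sin, cos) = (1, 0)
  q <- build_design(
    tibble::tibble(subject_id = "S1", hour_of_day = 5.5, is_weekend = FALSE,
                   mean_hr = 70, n_minutes = 60L),
    prof, terms = c("intercept", "h24"), random = "none")
  expect_equal(unname(q$X[1, "sin24"]), 1)
  expect_equal(unname(q$X[1, "cos24"]), 0, tolerance = 1e-12)
  # per-period identity: sin^2 + cos^2 = 1, summed over 4 periods
  quad <- d$X[, "sin24"]^2 + d$X[, "cos24"]^2 + d$X[, "sin12"]^2 +
    d$X[, "cos12"]^2 + d$X[, "sin8"]^2 + d$X[, "cos8"]^2 +
    d$X[, "sin6"]^2 + d$X[, "cos6"]^2
  expect_equal(quad, rep(4, nrow(d$X)))
  # balanced 24-hour design: harmonic columns sum to zero
  for (cn in c("sin24", "cos24", "sin12", "cos12", "sin8", "cos8",
               "sin6", "cos6")) {
    expect_equal(sum(d$X[, cn]), 0, tolerance = 1e-10)
  }
  expect_equal(ncol(d$X), 34)
})

test_that("design rejects unknown subjects and enforces term hierarchy", {
  prof <- fixture_profile()
  hourly <- tibble::tibble(subject_id = "GHOST", hour_of_day = 1,
                           is_weekend = FALSE, mean_hr = 70, n_minutes = 60L)
  expect_error(build_design(hourly, prof), class = "circastress_spec_error")
  expect_error(
    build_design(
      tibble::tibble(subject_id = "S1", hour_of_day = 1, is_weekend = FALSE,
                     mean_hr = 70, n_minutes = 60L),
      prof, terms = c("intercept", "gender:pss")),
    class = "circastress_spec_error")
})

test_that("AR(1) matrices have the power-law form and Markov inverse", {
  expect_equal(ar1_matrix(3, 0), diag(3))
  expect_equal(ar1_matrix(4, 0.5)[1, 3], 0.25)
  expect_equal(ar1_matrix(4, 0.5)[4, 1], 0.125)
  expect_error(ar1_matrix(3, 1), class = "circastress_domain_error")
  # the inverse of an AR(1) covariance is tridiagonal (Markov property)
  Rinv <- solve(ar1_matrix(5, 0.6))
  off <- Rinv[abs(row(Rinv) - col(Rinv)) > 1]
  expect_equal(off, rep(0, length(off)), tolerance = 1e-10)
})

test_that("the marginal log-likelihood equals a dense MVN evaluation", {
  prof <- tiny_cohort(2, 1, seed = 6)
  eff <- effect_config()
  sh <- simulate_hourly(prof, eff, seed = 6)
  # 2 subjects x <= 24 rows: drop weekend rows to stay under 50 observations
  hourly <- dplyr::filter(sh$hourly, hour_of_day < 12)
  for (random in c("none", "reduced", "final")) {
    d <- build_design(hourly, prof, random = random,
                      centers = c(age = eff$age_ref, pss = eff$pss_ref))
    expect_lte(d$n_obs, 50)
    re_var <- stats::setNames(seq_len(d$k_v) * 0.7, d$var_names)
    beta <- true_fixed_effects(eff)
    ll_pkg <- harmonic_loglik(d, beta, re_var, rho = 0.35, sigma2 = 1.8)
    ll_dense <- dense_loglik(d, beta, re_var, rho = 0.35, sigma2 = 1.8)
    expect_equal(ll_pkg, ll_dense, tolerance = 1e-8)
  }
})

test_that("with no random effects and rho 0 the likelihood is the OLS one", {
  prof <- tiny_cohort(3, 1, seed = 2)
  sh <- simulate_hourly(prof, effect_config(), seed = 2)
  d <- build_design(sh$hourly, prof, random = "none", ar1 = FALSE)
  beta <- rep(0, d$p); beta[1] <- 70
  s2 <- 9
  ll <- harmonic_loglik(d, beta, numeric(0), rho = 0, sigma2 = s2)
  resid <- d$y - as.numeric(d$X %*% beta)
  expect_equal(ll, sum(stats::dnorm(resid, 0, sqrt(s2), log = TRUE)))
})

test_that("the likelihood is location equivariant", {
  prof <- tiny_cohort(2, 1, seed = 9)
  sh <- simulate_hourly(prof, effect_config(), seed = 9)
  d1 <- build_design(sh$hourly, prof, random = "reduced")
  shifted <- dplyr::mutate(sh$hourly, mean_hr = mean_hr + 11)
  d2 <- build_design(shifted, prof, random = "reduced")
  beta1 <- c(70, rep(0.1, d1$p - 1))
  beta2 <- beta1; beta2[1] <- beta2[1] + 11
  re <- c(4, 1)
  expect_equal(harmonic_loglik(d1, beta1, re, 0.3, 2),
               harmonic_loglik(d2, beta2, re, 0.3, 2))
})

test_that("null data yield near-zero effects and autocorrelation", {
  prof <- tiny_cohort(30, 13, seed = 14)
  hourly <- tidyr::crossing(subject_id = prof$subject_id, hour_of_day = 0:23,
                            is_weekend = c(FALSE, TRUE))
  withr::with_seed(14, {
    hourly$mean_hr <- rnorm(nrow(hourly))
  })
  hourly$n_minutes <- 60L
  f <- suppressWarnings(fit_harmonic_model(hourly, prof, random = "reduced"))
  expect_lt(max(abs(f$beta / f$se)), 4)
  expect_lt(abs(f$rho), 0.1)
  expect_lt(max(sqrt(f$re_var)), 0.2)
})

test_that("the ML fit matches nlme::lme with corAR1 on the same model", {
  skip_if_not_installed("nlme")
  prof <- tiny_cohort(20, 9, seed = 21)
  sh <- simulate_hourly(prof, effect_config(), seed = 21)
  d <- build_design(sh$hourly, prof, random = "reduced")
  f <- fit_harmonic_model(design = d)
  dat <- as.data.frame(d$X[, -1])
  names(dat) <- paste0("x", seq_len(ncol(dat)))
  dat$y <- d$y
  dat$subj <- d$data$subject_id
  dat$dt <- ifelse(d$data$is_weekend, "we", "wd")
  dat$pos <- d$data$hour_of_day
  fm <- stats::as.formula(paste("y ~", paste(names(dat)[seq_len(d$p - 1)],
                                             collapse = "+")))
  lf <- nlme::lme(fm, random = ~ 1 | subj / dt,
                  correlation = nlme::corAR1(form = ~ pos | subj / dt),
                  data = dat, method = "ML",
                  control = nlme::lmeControl(maxIter = 200, msMaxIter = 200))
  expect_equal(f$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(nlme::fixed.effects(lf)),
               tolerance = 1e-4)
})

test_that("24 h harmonic coefficients are recovered within 10 percent", {
  eff <- effect_config()
  prof <- generate_cohort(cohort_config(n_subjects = 120, n_female = 52,
                                        seed = 33))
  sh <- simulate_hourly(prof, eff, seed = 33)
  f <- suppressWarnings(
    fit_harmonic_model(sh$hourly, prof, random = "final",
                       centers = c(age = eff$age_ref, pss = eff$pss_ref)))
  truth <- true_fixed_effects(eff)
  for (cn in c("sin24", "cos24")) {
    expect_lt(abs(f$beta[cn] - truth[cn]), 0.1 * abs(truth[cn]))
  }
})

test_that("likelihood-ratio tests have the right structure", {
  prof <- tiny_cohort(16, 7, seed = 17)
  sh <- simulate_hourly(prof, effect_config(), seed = 17)
  full_terms <- final_model_terms()
  d_full <- build_design(sh$hourly, prof, terms = full_terms,
                         random = "reduced")
  f_full <- fit_harmonic_model(design = d_full)

  # dropping every PSS term removes exactly 6 fixed-effect parameters
  red <- drop_terms_with(full_terms, "pss")
  f_red <- fit_harmonic_model(sh$hourly, prof, terms = red,
                              random = "reduced")
  tt <- lrt_compare(f_full, f_red)
  expect_equal(tt$df, 6L)
  expect_gte(tt$chisq, 0)
  expect_equal(tt$chisq, 2 * (f_full$loglik - f_red$loglik))

  # identical specs: chisq 0, p 1
  same <- lrt_compare(f_full, f_full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # gender x circadian (within the two-way model, per the hierarchy rule)
  two_way <- setdiff(full_terms, c("gender:pss:h24", "age:weekend:h24"))
  f_two <- fit_harmonic_model(sh$hourly, prof, terms = two_way,
                              random = "reduced")
  f_nog <- fit_harmonic_model(sh$hourly, prof,
                              terms = setdiff(two_way, "gender:h24"),
                              random = "reduced")
  expect_equal(lrt_compare(f_two, f_nog)$df, 2L)

  # non-nested comparison is a contract error
  expect_error(lrt_compare(f_red, f_full),
               class = "circastress_contract_error")
})

test_that("the model ladder improves with the circadian harmonic and is monotone", {
  prof <- tiny_cohort(16, 7, seed = 25)
  sh <- simulate_hourly(prof, effect_config(), seed = 25)
  lad <- suppressWarnings(model_ladder(sh$hourly, prof, random = "reduced"))
  expect_equal(nrow(lad), 11)
  expect_lt(lad$aic[lad$layer == "h24"], lad$aic[lad$layer == "hour"])
  # logLik never decreases as nested terms are added
  expect_true(all(diff(lad$loglik) > -1e-3))
  # the final layer is the final model
  final_fit <- attr(lad, "final_fit")
  expect_identical(final_fit$terms, final_model_terms())
  expect_equal(sum(lad$best_aic), 1)
})

test_that("AIC arithmetic and tidiers are consistent", {
  prof <- tiny_cohort(8, 4, seed = 31)
  sh <- simulate_hourly(prof, effect_config(), seed = 31)
  f <- suppressWarnings(fit_harmonic_model(sh$hourly, prof, random = "reduced"))
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  expect_equal(f$k, 34 + 2 + 1 + 1)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(nrow(td), 34)
  gl <- glance(f)
  expect_equal(gl$AIC, f$aic)
  expect_equal(gl$nobs, f$n_obs)
  vp <- tidy(f, effects = "ran_pars")
  expect_true("ar1_rho" %in% vp$term)
  ll <- stats::logLik(f)
  expect_equal(as.numeric(ll), f$loglik)
  expect_equal(attr(ll, "df"), f$k)
})

test_that("rank-deficient fixed designs raise an error naming aliased columns", {
  prof <- tiny_cohort(6, 6, seed = 2)  # all female: gender column aliased
  sh <- simulate_hourly(prof, effect_config(), seed = 2)
  expect_error(
    fit_harmonic_model(sh$hourly, prof,
                       terms = c("intercept", "hour", "h24", "weekend",
                                 "gender"),
                       random = "reduced"),
    regexp = "gender", class = "circastress_rank_error")
})
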