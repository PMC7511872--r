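## Maximum-likelihood fitting of the harmonic mixed-effects model.
##
## The marginal model for the stacked series of subject i is
##   y_i ~ Normal(X_i beta, Z_i Psi Z_i' + sigma2 * R_i(rho)),
## with diagonal Psi and R_i block-AR(1) per day-type series. The fit
## profiles beta (generalized least squares) and sigma2 (residual scale)
## out of the likelihood and optimizes only the log relative variances
## (Psi / sigma2) and atanh(rho) with a bounded quasi-Newton method.

## Profiled evaluation. theta = c(log relative variances, atanh(rho)).
profiled_eval <- function(theta, design) {
  kv <- design$k_v
  relvar <- if (kv > 0) exp(theta[seq_len(kv)]) else numeric(0)
  rho <- if (design$ar1) tanh(theta[kv + 1L]) else 0
  p <- design$p
  A <- matrix(0, p, p)
  b <- numeric(p)
  yty <- 0
  logdet <- 0
  N <- design$n_obs
  for (g in design$groups) {
    W <- ar1_block(g$series_len, rho)
    if (ncol(g$Z) > 0) {
      W <- W + g$Z %*% (relvar[g$varmap] * t(g$Z))
    }
    U <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    logdet <- logdet + g$n_g * 2 * sum(log(diag(U)))
    Bt <- backsolve(U, g$Bmat, transpose = TRUE)
    Yt <- backsolve(U, g$yflat, transpose = TRUE)
    Cm <- crossprod(Bt, Yt)
    A <- A + crossprod(Bt) * g$SS
    b <- b + rowSums(Cm * g$tSmat)
    yty <- yty + sum(Yt^2)
  }
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rss <- max(yty - sum(beta * b), 1e-12)
  sigma2 <- rss / N
  ll <- -N / 2 * (log(2 * pi) + 1 + log(sigma2)) - logdet / 2
  list(ll = ll, beta = beta, A = A, sigma2 = sigma2, rho = rho,
       relvar = relvar)
}

#' Marginal log-likelihood of the harmonic mixed model
#'
#' Evaluates the exact joint Gaussian log-density of the hourly
#' observations for explicit parameter values: fixed effects `beta`,
#' random-effect variances `re_var` (one per variance component of the
#' design, in `design$var_names` order), AR(1) coefficient `rho` and
#' residual variance `sigma2`. With all random variances zero and
#' `rho = 0` this reduces to the ordinary independent-Normal
#' log-likelihood.
#'
#' @param design A [build_design()] object.
#' @param beta Fixed-effect vector (length `design$p`).
#' @param re_var Random-effect variances (length `design$k_v`), bpm^2.
#' @param rho AR(1) coefficient, `|rho| < 1`.
#' @param sigma2 Residual variance, > 0.
#' @return The log-likelihood (scalar).
#' @export
harmonic_loglik <- function(design, beta, re_var = numeric(design$k_v),
                            rho = 0, sigma2) {
  stopifnot(inherits(design, "harmonic_design"),
            length(beta) == design$p, length(re_var) == design$k_v,
            sigma2 > 0)
  if (abs(rho) >= 1) {
    abort("`rho` must satisfy |rho| < 1.", class = "circastress_domain_error")
  }
  if (any(re_var < 0)) {
    abort("Random-effect variances must be non-negative.",
          class = "circastress_domain_error")
  }
  ll <- 0
  for (g in design$groups) {
    V <- sigma2 * ar1_block(g$series_len, rho)
    if (ncol(g$Z) > 0) V <- V + g$Z %*% (re_var[g$varmap] * t(g$Z))
    U <- tryCatch(chol(V), error = function(e) {
      abort("Marginal covariance is not positive definite for these parameters.",
            class = "circastress_fit_error")
    })
    r <- g$yflat - matrix(matrix(g$Xflat, nrow = g$m * g$n_g) %*% beta,
                          nrow = g$m)
    q <- backsolve(U, r, transpose = TRUE)
    ll <- ll - 0.5 * (g$m * g$n_g * log(2 * pi) +
                        g$n_g * 2 * sum(log(diag(U))) + sum(q^2))
  }
  ll
}

#' Fit the harmonic mixed-effects model by maximum likelihood
#'
#' Maximizes the marginal Gaussian likelihood over the fixed effects, the
#' diagonal random-effect variances, the AR(1) coefficient and the residual
#' variance. Fixed effects and residual scale are profiled out exactly at
#' every covariance iterate; the remaining parameters are optimized on an
#' unconstrained scale (log variance ratios, atanh rho) with at most
#' `max_iter` iterations. Non-convergence is reported in the result
#' (`converged = FALSE`), never hidden.
#'
#' @inheritParams build_design
#' @param design Alternatively, a prebuilt [build_design()] object
#'   (overrides `hourly`/`subjects`/`terms`/`random`/`ar1`).
#' @param hourly,subjects Data for [build_design()].
#' @param init Optional numeric start for `c(log(Psi/sigma2), atanh(rho))`.
#' @param max_iter Optimizer iteration cap (default 200).
#' @param drop_aliased Degrade gracefully on rank-deficient fixed designs
#'   (tiny or degenerate cohorts) by dropping the aliased columns with a
#'   warning instead of raising an error.
#' @return An object of class `harmonic_fit`: fixed-effect estimates and
#'   covariance, variance components (bpm^2), `rho`, `sigma2`, `loglik`,
#'   `aic`, the free-parameter count `k`, `n_obs` and a convergence flag.
#' @export
fit_harmonic_model <- function(hourly = NULL, subjects = NULL,
                               terms = final_model_terms(),
                               random = c("final", "reduced", "none"),
                               ar1 = TRUE, centers = NULL,
                               design = NULL, init = NULL,
                               max_iter = 200L, drop_aliased = FALSE) {
  if (is.null(design)) {
    design <- build_design(hourly, subjects, terms = terms, random = random,
                           ar1 = ar1, centers = centers)
  }
  stopifnot(inherits(design, "harmonic_design"))
  qr_x <- qr(design$X)
  if (qr_x$rank < design$p) {
    aliased <- design$colnames[qr_x$pivot[(qr_x$rank + 1):design$p]]
    if (!drop_aliased) {
      abort(sprintf("Fixed design is rank deficient; aliased column(s): %s.",
                    paste(aliased, collapse = ", ")),
            class = "circastress_rank_error")
    }
    warn(sprintf("Dropping aliased fixed-effect column(s): %s.",
                 paste(aliased, collapse = ", ")))
    design <- drop_design_columns(design, sort(qr_x$pivot[seq_len(qr_x$rank)]))
  }
  if (design$n_subjects < 2 && design$random != "none") {
    abort("At least two subjects are required to fit random effects.",
          class = "circastress_spec_error")
  }

  n_theta <- design$k_v + as.integer(design$ar1)
  if (n_theta == 0) {
    ev <- profiled_eval(numeric(0), design)
    opt <- list(convergence = 0L, iterations = 0L)
  } else {
    theta0 <- init %||% c(rep(log(0.5), design$k_v),
                          if (design$ar1) atanh(0.2))
    if (length(theta0) != n_theta) {
      abort(sprintf("`init` must have length %d.", n_theta),
            class = "circastress_config_error")
    }
    obj <- function(th) {
      ev <- profiled_eval(th, design)
      if (is.null(ev) || !is.finite(ev$ll)) return(1e10)
      -ev$ll
    }
    lower <- c(rep(-20, design$k_v), if (design$ar1) -3)
    upper <- c(rep(12, design$k_v), if (design$ar1) 3)
    opt <- nlminb(theta0, obj, lower = lower, upper = upper,
                  control = list(iter.max = max_iter, eval.max = 10 * max_iter,
                                 rel.tol = 1e-10))
    ev <- profiled_eval(opt$par, design)
    if (is.null(ev)) {
      abort("Likelihood evaluation failed at the optimum.",
            class = "circastress_fit_error")
    }
  }

  cov_beta <- ev$sigma2 * solve(ev$A)
  se <- sqrt(diag(cov_beta))
  k <- design$p + design$k_v + as.integer(design$ar1) + 1L
  converged <- opt$convergence == 0 &&
    (is.null(opt$iterations) || opt$iterations < max_iter)
  if (!converged) {
    warn("fit_harmonic_model: optimizer did not converge; inspect `$converged`.")
  }
  structure(list(
    beta = setNames(as.numeric(ev$beta), design$colnames),
    se = setNames(se, design$colnames),
    cov_beta = cov_beta,
    re_var = setNames(ev$relvar * ev$sigma2,
                      design$var_names),
    rho = if (design$ar1) ev$rho else NA_real_,
    sigma2 = ev$sigma2,
    loglik = ev$ll,
    k = k,
    aic = 2 * k - 2 * ev$ll,
    n_obs = design$n_obs,
    n_subjects = design$n_subjects,
    converged = converged,
    terms = design$terms,
    random = design$random,
    ar1 = design$ar1,
    centers = design$centers,
    opt = opt
  ), class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> ML, %d obs / %d subjects\n", x$n_obs,
              x$n_subjects))
  cat(sprintf("  logLik %.2f  AIC %.2f  (k = %d)%s\n", x$loglik, x$aic, x$k,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  sigma %.3f bpm, AR(1) rho %s\n", sqrt(x$sigma2),
              if (is.na(x$rho)) "-" else sprintf("%.3f", x$rho)))
  if (length(x$re_var) > 0) {
    cat("  random-effect SDs (bpm):\n")
    sds <- sqrt(x$re_var)
    for (nm in names(sds)) cat(sprintf("    %-24s %.3f\n", nm, sds[nm]))
  }
  invisible(x)
}

#' @export
logLik.harmonic_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.harmonic_fit <- function(object, ...) object$n_obs

#' Reported harmonic amplitudes and acrophases
#'
#' Converts the sin/cos coefficient pairs of a fit back to amplitude
#' (`sqrt(a^2 + b^2)`, bpm) and acrophase (hour of peak) per period, for
#' the reference stratum (male, workday, covariates at their centres).
#'
#' @param fit A [fit_harmonic_model()] result.
#' @return Tibble with `period`, `amplitude`, `acrophase`.
#' @export
harmonic_amplitudes <- function(fit) {
  stopifnot(inherits(fit, "harmonic_fit"))
  out <- map(names(harmonic_periods), function(nm) {
    p <- harmonic_periods[[nm]]
    a <- fit$beta[paste0("sin", p)]
    b <- fit$beta[paste0("cos", p)]
    if (anyNA(c(a, b))) return(NULL)
    phi <- (atan2(a, b) * p / (2 * pi)) %% p
    tibble(period = p, amplitude = sqrt(a^2 + b^2), acrophase = phi)
  })
  bind_rows(out)
}
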