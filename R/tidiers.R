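## broom-style tidiers for fitted harmonic mixed models.

#' Tidy a harmonic mixed-model fit
#'
#' @param x A [fit_harmonic_model()] result.
#' @param effects `"fixed"` (default) for the fixed-effect table or
#'   `"ran_pars"` for variance components / AR(1) / residual SD.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble; for fixed effects: `term`, `estimate`, `std.error`,
#'   `statistic` (Wald z), `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.harmonic_fit <- function(x, effects = c("fixed", "ran_pars"),
                              conf.level = 0.95, ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    z <- x$beta / x$se
    return(tibble(
      term = names(x$beta),
      estimate = unname(x$beta),
      std.error = unname(x$se),
      statistic = unname(z),
      p.value = unname(2 * pnorm(-abs(z))),
      conf.low = unname(x$beta - zq * x$se),
      conf.high = unname(x$beta + zq * x$se)
    ))
  }
  bind_rows(
    tibble(term = paste0("sd_", names(x$re_var)),
           estimate = sqrt(unname(x$re_var))),
    tibble(term = "ar1_rho", estimate = x$rho),
    tibble(term = "sd_residual", estimate = sqrt(x$sigma2))
  )
}

#' Glance at a harmonic mixed-model fit
#'
#' @param x A [fit_harmonic_model()] result.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `df` (free parameters),
#'   `nobs`, `n_subjects`, `sigma`, `rho`, `converged`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, AIC = x$aic, df = x$k, nobs = x$n_obs,
    n_subjects = x$n_subjects, sigma = sqrt(x$sigma2), rho = x$rho,
    converged = x$converged
  )
}
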