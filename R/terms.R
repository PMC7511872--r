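## Fixed-effect term machinery shared by the generator and the model.
##
## A "term" is a label such as "h24", "gender", or "gender:pss:h24". Harmonic
## terms expand into a sin/cos column pair (cosinor parameterization, linear
## in its coefficients); every other factor contributes a single column.
## Covariate coding: gender 0 = male (reference), 1 = female; weekend 0 =
## workday (Friday/Monday), 1 = weekend (Saturday/Sunday); age and PSS are
## centred; the hour enters both linearly (centred at 12 h) and through the
## harmonics.

#' Fixed-effect terms of the final heart-rate model
#'
#' The ordered term list of the full model: hour of day (linear), the four
#' harmonics (24/12/8/6 h), weekend, gender, age and PSS main effects, the
#' weekend-by-harmonic, gender/age/PSS-by-circadian, gender-by-PSS and
#' age-by-weekend two-way interactions, and the two three-way interactions
#' (gender x PSS x 24 h harmonic; age x weekend x 24 h harmonic).
#'
#' @return Character vector of term labels.
#' @export
final_model_terms <- function() {
  c("intercept", "hour", "h24", "h12", "h8", "h6",
    "weekend", "gender", "age", "pss",
    "weekend:h24", "weekend:h12", "weekend:h8", "weekend:h6",
    "gender:h24", "age:h24", "pss:h24",
    "gender:pss", "age:weekend",
    "gender:pss:h24", "age:weekend:h24")
}

term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

is_harmonic_factor <- function(f) f %in% period_names

## Hierarchy rule: an interaction may only appear when all of its marginal
## (lower-order) terms are present.
validate_term_hierarchy <- function(terms) {
  for (term in terms) {
    f <- term_factors(term)
    if (length(f) < 2) next
    for (k in seq_len(length(f) - 1)) {
      subs <- utils::combn(f, k, paste, collapse = ":")
      missing <- setdiff(subs, terms)
      if (length(missing) > 0) {
        abort(sprintf(
          "Term `%s` violates the hierarchy rule: missing marginal term(s) %s.",
          term, paste0("`", missing, "`", collapse = ", ")),
          class = "circastress_spec_error")
      }
    }
  }
  invisible(terms)
}

## Sin/cos basis for the four harmonics at time-of-day t (hours, continuous).
harmonic_basis <- function(t_hours, periods = harmonic_periods) {
  out <- lapply(names(periods), function(nm) {
    p <- periods[[nm]]
    m <- cbind(sin(2 * pi * t_hours / p), cos(2 * pi * t_hours / p))
    colnames(m) <- paste0(c("sin", "cos"), p)
    m
  })
  do.call(cbind, out)
}

## Expand one term into its design column(s).
## df must carry: t (hour of day, continuous), weekend01, gender01, age_c,
## pss_c.
term_matrix <- function(term, df) {
  f <- term_factors(term)
  harm <- f[is_harmonic_factor(f)]
  scal <- f[!is_harmonic_factor(f)]
  if (length(harm) > 1) {
    abort(sprintf("Term `%s` contains more than one harmonic factor.", term),
          class = "circastress_spec_error")
  }
  scalar_col <- function(nm) {
    switch(nm,
      intercept = rep(1, nrow(df)),
      hour = df$t - 12,
      weekend = df$weekend01,
      gender = df$gender01,
      age = df$age_c,
      pss = df$pss_c,
      abort(sprintf("Unknown term factor `%s`.", nm),
            class = "circastress_spec_error"))
  }
  sc <- rep(1, nrow(df))
  for (nm in scal) sc <- sc * scalar_col(nm)
  if (length(harm) == 0) {
    m <- matrix(sc, ncol = 1)
    colnames(m) <- term
    return(m)
  }
  p <- harmonic_periods[[harm]]
  hb <- cbind(sin(2 * pi * df$t / p), cos(2 * pi * df$t / p))
  m <- hb * sc
  base <- paste0(c("sin", "cos"), p)
  pre <- setdiff(f, harm)
  colnames(m) <- if (length(pre) == 0) base else
    paste(paste(pre, collapse = ":"), base, sep = ":")
  m
}

## Full fixed-effect matrix for a term list, columns in term order.
build_fixed_matrix <- function(df, terms) {
  validate_term_hierarchy(terms)
  do.call(cbind, lapply(terms, term_matrix, df = df))
}

#' True fixed-effect coefficients implied by an effect configuration
#'
#' Translates the generator's amplitude/acrophase parameterization into the
#' sin/cos coefficient vector of the fitted model, so simulated data have an
#' exact known truth for every fixed-effect column. An amplitude
#' `A*cos(2*pi*(t - phi)/p)` contributes `A*sin(2*pi*phi/p)` to the sin
#' column and `A*cos(2*pi*phi/p)` to the cos column; linear amplitude
#' modulations (weekend, PSS by gender, age by day-type) map onto the
#' corresponding interaction columns. Terms the generator does not modulate
#' (linear hour, gender x circadian amplitude, the level-only interactions)
#' are exactly zero.
#'
#' Valid when the design is centred at the generator's own reference values
#' (`age_ref`, `pss_ref`).
#'
#' @param effects An [effect_config()].
#' @param terms Term labels, default [final_model_terms()].
#' @return Named numeric vector over the expanded design columns.
#' @export
true_fixed_effects <- function(effects, terms = final_model_terms()) {
  stopifnot(inherits(effects, "effect_config"))
  phase_sc <- function(pn) {
    p <- harmonic_periods[[pn]]
    th <- 2 * pi * effects$harmonic_phases[[pn]] / p
    c(sin = sin(th), cos = cos(th))
  }
  coefs_for <- function(term) {
    f <- term_factors(term)
    harm <- f[is_harmonic_factor(f)]
    if (length(harm) == 0) {
      val <- switch(term,
        intercept = effects$baseline_hr,
        gender = effects$gender_shift,
        0)
      return(setNames(val, term))
    }
    sc <- phase_sc(harm)
    amp <- switch(term,
      h24 = , h12 = , h8 = , h6 = effects$harmonic_amplitudes[[term]],
      "weekend:h24" = effects$weekend_harmonic_delta[["h24"]],
      "weekend:h12" = effects$weekend_harmonic_delta[["h12"]],
      "weekend:h8" = effects$weekend_harmonic_delta[["h8"]],
      "weekend:h6" = effects$weekend_harmonic_delta[["h6"]],
      "age:h24" = effects$age_h24_slope_workday,
      "pss:h24" = effects$pss_h24_slope_male,
      "gender:pss:h24" = effects$pss_h24_slope_female - effects$pss_h24_slope_male,
      "age:weekend:h24" = effects$age_h24_slope_weekend - effects$age_h24_slope_workday,
      0)
    p <- harmonic_periods[[harm]]
    base <- paste0(c("sin", "cos"), p)
    pre <- setdiff(f, harm)
    nms <- if (length(pre) == 0) base else
      paste(paste(pre, collapse = ":"), base, sep = ":")
    setNames(amp * sc, nms)
  }
  unlist(lapply(terms, coefs_for))
}
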