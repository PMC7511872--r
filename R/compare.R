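## Model comparison: nested likelihood-ratio tests and the additive model
## ladder (AIC / logLik per layer).

#' Likelihood-ratio test between nested ML fits
#'
#' `chisq = 2 * (logLik_full - logLik_reduced)` compared against a
#' chi-square with `df` equal to the difference in free-parameter count.
#' Both fits must be ML fits of the same data (same observation count) with
#' the reduced fixed terms a subset of the full ones and identical random /
#' correlation structure.
#'
#' @param fit_full,fit_reduced [fit_harmonic_model()] results.
#' @param term Label for the tested term block (defaults to the dropped
#'   terms).
#' @return A one-row tibble: `term`, `chisq`, `df`, `p`.
#' @export
lrt_compare <- function(fit_full, fit_reduced, term = NULL) {
  stopifnot(inherits(fit_full, "harmonic_fit"),
            inherits(fit_reduced, "harmonic_fit"))
  if (!all(fit_reduced$terms %in% fit_full$terms) ||
      fit_reduced$random != fit_full$random ||
      fit_reduced$ar1 != fit_full$ar1) {
    abort("`fit_reduced` must be nested in `fit_full` (same random/correlation structure, subset of fixed terms).",
          class = "circastress_contract_error")
  }
  if (fit_full$n_obs != fit_reduced$n_obs) {
    abort("Fits compare different data (observation counts differ).",
          class = "circastress_contract_error")
  }
  df <- fit_full$k - fit_reduced$k
  dropped <- setdiff(fit_full$terms, fit_reduced$terms)
  if (df == 0) {
    return(tibble(term = term %||% "(identical)", chisq = 0, df = 0L, p = 1))
  }
  chisq <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  tibble(
    term = term %||% paste(dropped, collapse = " + "),
    chisq = chisq,
    df = as.integer(df),
    p = pchisq(chisq, df, lower.tail = FALSE)
  )
}

#' Drop every term involving a factor
#'
#' Helper for building nested comparisons: removes all terms whose factor
#' list contains `factor` (e.g. `"pss"` removes the PSS main effect, the
#' gender x PSS and PSS x circadian interactions and the three-way term —
#' six fixed-effect columns for the final model).
#'
#' @param terms Character vector of term labels.
#' @param factor Factor name to purge.
#' @return The reduced term vector.
#' @export
drop_terms_with <- function(terms, factor) {
  keep(terms, ~ !factor %in% term_factors(.x))
}

## The additive build order of the model: each layer's terms.
ladder_layers <- function() {
  list(
    hour = c("intercept", "hour"),
    h24 = "h24", h12 = "h12", h8 = "h8", h6 = "h6",
    weekend = "weekend", gender = "gender", age = "age", pss = "pss",
    two_way = c("weekend:h24", "weekend:h12", "weekend:h8", "weekend:h6",
                "gender:h24", "age:h24", "pss:h24", "gender:pss",
                "age:weekend"),
    three_way = c("gender:pss:h24", "age:weekend:h24")
  )
}

#' Fit the additive model ladder
#'
#' Fits the sequence of nested models built by adding, in order: the linear
#' hour, the 24/12/8/6 h harmonics, weekend, gender, age, PSS, the two-way
#' interactions, and the three-way interactions (the final model). Reports
#' log-likelihood and AIC per layer and flags the AIC-minimal layer.
#' Layers that fail to converge are recorded (`converged = FALSE`) and the
#' ladder continues.
#'
#' @inheritParams build_design
#' @param random Random structure used for every layer (default
#'   `"reduced"`: intercepts + AR(1), which keeps the ladder desk-scale).
#' @param max_iter Optimizer cap per layer.
#' @return Tibble: `layer`, `terms_added`, `k`, `loglik`, `aic`,
#'   `converged`, `best_aic`; the fitted final layer is attached as the
#'   `final_fit` attribute.
#' @export
model_ladder <- function(hourly, subjects, random = "reduced",
                         ar1 = TRUE, centers = NULL, max_iter = 200L) {
  layers <- ladder_layers()
  terms <- character(0)
  rows <- vector("list", length(layers))
  fit <- NULL
  for (j in seq_along(layers)) {
    terms <- c(terms, layers[[j]])
    fit_j <- tryCatch(
      fit_harmonic_model(hourly, subjects, terms = terms, random = random,
                         ar1 = ar1, centers = centers, max_iter = max_iter),
      error = function(e) NULL)
    rows[[j]] <- tibble(
      layer = names(layers)[j],
      terms_added = paste(layers[[j]], collapse = " + "),
      k = if (is.null(fit_j)) NA_integer_ else fit_j$k,
      loglik = if (is.null(fit_j)) NA_real_ else fit_j$loglik,
      aic = if (is.null(fit_j)) NA_real_ else fit_j$aic,
      converged = !is.null(fit_j) && fit_j$converged
    )
    if (!is.null(fit_j)) fit <- fit_j
  }
  out <- bind_rows(rows)
  out$best_aic <- !is.na(out$aic) & out$aic == min(out$aic, na.rm = TRUE)
  attr(out, "final_fit") <- fit
  out
}

#' PSS likelihood-ratio test
#'
#' Compares the final model with the same model stripped of every
#' PSS-containing term (main effect, gender x PSS, PSS x circadian, gender
#' x PSS x circadian: six fixed-effect parameters).
#'
#' @inheritParams build_design
#' @param random Random structure for both fits.
#' @param max_iter Optimizer cap.
#' @param drop_aliased Passed to [fit_harmonic_model()]: degrade gracefully
#'   on degenerate cohorts.
#' @return A one-row [lrt_compare()] tibble; the two fits are attached as
#'   attributes `fit_full` and `fit_reduced`.
#' @export
pss_lrt <- function(hourly, subjects, random = "reduced", centers = NULL,
                    max_iter = 200L, drop_aliased = FALSE) {
  full_terms <- final_model_terms()
  red_terms <- drop_terms_with(full_terms, "pss")
  design_full <- build_design(hourly, subjects, terms = full_terms,
                              random = random, centers = centers)
  design_red <- build_design(hourly, subjects, terms = red_terms,
                             random = random, centers = centers)
  fit_full <- fit_harmonic_model(design = design_full, max_iter = max_iter,
                                 drop_aliased = drop_aliased)
  fit_red <- fit_harmonic_model(design = design_red, max_iter = max_iter,
                                drop_aliased = drop_aliased)
  out <- lrt_compare(fit_full, fit_red, term = "pss (all terms)")
  attr(out, "fit_full") <- fit_full
  attr(out, "fit_reduced") <- fit_red
  out
}
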