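## The six estimation strategies compared in the simulation study, plus
## propensity-score construction and the instrument diagnostics.
##
## Strategy designs for the proportional-odds outcome model:
##   a  T                                     (univariable)
##   b  C_obs + T                             (covariate adjustment)
##   c  PS + T                                (propensity-score adjustment)
##   d  Z                                     (IV analysis)
##   e  Z + hospital adjustment               (adjusted IV)
##   f  Z + hospital adjustment + C_obs + U   (fully adjusted control model)
## Strategies a-c report the coefficient on T (a treatment effect);
## d-f report the coefficient on Z (an effect of treatment *preference*,
## which is a different estimand and is labelled as such).

STRATEGIES <- c("a", "b", "c", "d", "e", "f")

#' Propensity score from the observed confounders
#'
#' Logistic regression of treatment on the observed covariate block only
#' (GCS motor, age, sex); the hypothetically unobserved confounders are
#' deliberately excluded, mimicking what an analyst without them could fit.
#'
#' @param dataset a `simulated_dataset`.
#' @param scale `"logit"` (default) returns the fitted linear predictor,
#'   the form in which the score enters strategy c; `"prob"` returns
#'   fitted probabilities.
#' @param warn_drop passed to [fit_logistic()].
#' @return numeric vector of per-patient scores with the underlying
#'   `adjiv_fit` attached as attribute `"fit"`.
#' @export
compute_propensity <- function(dataset, scale = c("logit", "prob"), warn_drop = TRUE) {
  scale <- match.arg(scale)
  X <- encode_design(dataset, "observed")
  fit <- fit_logistic(X, dataset$T, warn_drop = warn_drop)
  keep <- intersect(colnames(X), names(fit$coefficients))
  lp <- drop(X[, keep, drop = FALSE] %*% fit$coefficients[keep]) +
    fit$coefficients["(Intercept)"]
  out <- if (scale == "logit") lp else stats::plogis(lp)
  attr(out, "fit") <- fit
  out
}

strategy_design <- function(strategy, dataset, hospitals,
                            hospital_adjust = c("performance", "dummies"),
                            warn_drop = TRUE) {
  hospital_adjust <- match.arg(hospital_adjust)
  hosp_block <- function() {
    if (hospital_adjust == "dummies") {
      z_by_h <- tapply(dataset$Z, dataset$hospital_id, function(z) diff(range(z)))
      if (all(z_by_h < 1e-12))
        stop_usage("hospital dummies are exactly collinear with an ",
                   "instrument that is constant within hospital; use ",
                   "hospital_adjust = 'performance' (adjust for the ",
                   "hospital performance covariate) instead")
      ids <- factor(dataset$hospital_id)
      X <- stats::model.matrix(~ ids)[, -1, drop = FALSE]
      colnames(X) <- paste0("hospital", levels(ids)[-1])
      X
    } else {
      eta <- hospitals$performance[match(dataset$hospital_id, hospitals$hospital_id)]
      matrix(eta, ncol = 1, dimnames = list(NULL, "hospital_performance"))
    }
  }
  switch(strategy,
         a = cbind(T = dataset$T),
         b = cbind(encode_design(dataset, "observed"), T = dataset$T),
         c = cbind(PS = as.numeric(compute_propensity(dataset, warn_drop = warn_drop)),
                   T = dataset$T),
         d = cbind(Z = dataset$Z),
         e = cbind(Z = dataset$Z, hosp_block()),
         f = cbind(Z = dataset$Z, hosp_block(),
                   encode_design(dataset, "observed"),
                   encode_design(dataset, "unobserved")),
         stop_usage("unknown strategy '", strategy, "'; use one of ",
                    paste(STRATEGIES, collapse = ", ")))
}

#' Estimate the treatment (or preference) effect with one strategy
#'
#' Fits the proportional-odds outcome model with the design of the
#' requested strategy and extracts the coefficient of interest: `T` for
#' strategies a-c, `Z` for d-f.  Because the instrument is constant within
#' hospital, per-hospital indicator dummies would be exactly collinear
#' with it; the default hospital adjustment for strategies e/f therefore
#' enters the hospital's performance value as a single continuous
#' covariate (the common cause itself, knowable in simulation).
#' `hospital_adjust = "dummies"` is available for datasets whose
#' instrument varies within hospital and raises an identifiability error
#' otherwise.
#'
#' @param strategy one of `"a"` to `"f"`.
#' @param dataset a `simulated_dataset`.
#' @param hospitals the matching `hospital_table`; defaults to the one
#'   attached to `dataset`.
#' @param hospital_adjust `"performance"` (default) or `"dummies"`.
#' @param warn_drop warn when collinear columns (e.g. an all-zero
#'   performance column in scenarios without a hospital effect) are
#'   dropped.
#' @return an object of class `effect_estimate`: a one-row `data.frame`
#'   with `strategy`, `estimand` (`"treatment_effect"` or
#'   `"preference_effect"`), `beta`, `se`, `converged`; the full
#'   `adjiv_fit` is attached as attribute `"fit"`.  If the coefficient of
#'   interest was dropped by the collinearity screen (e.g. a constant
#'   instrument), `beta`/`se` are `NA` and `converged` is `FALSE`.
#' @export
estimate_effect <- function(strategy, dataset, hospitals = attr(dataset, "hospitals"),
                            hospital_adjust = c("performance", "dummies"),
                            warn_drop = TRUE) {
  strategy <- as.character(strategy)
  if (!strategy %in% STRATEGIES)
    stop_usage("unknown strategy '", strategy, "'; use one of ",
               paste(STRATEGIES, collapse = ", "))
  if (strategy %in% c("e", "f") && is.null(hospitals))
    stop_usage("strategies e/f need the hospital table for the hospital adjustment")
  X <- strategy_design(strategy, dataset, hospitals,
                       hospital_adjust = hospital_adjust, warn_drop = warn_drop)
  fit <- fit_proportional_odds(X, dataset$Y, warn_drop = warn_drop)
  target <- if (strategy %in% c("a", "b", "c")) "T" else "Z"
  estimand <- if (target == "T") "treatment_effect" else "preference_effect"
  beta <- unname(fit$coefficients[target])
  se <- unname(fit$se[target])
  converged <- fit$converged && target %in% names(fit$coefficients) && !is.na(beta)
  out <- data.frame(strategy = strategy, estimand = estimand,
                    beta = if (target %in% names(fit$coefficients)) beta else NA_real_,
                    se = if (target %in% names(fit$coefficients)) se else NA_real_,
                    converged = converged)
  attr(out, "fit") <- fit
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Instrument relevance: pseudo-R-squared of treatment on preference
#'
#' Nagelkerke R^2 of the logistic regression of treatment on the
#' instrument, the study's check of the relevance assumption.
#'
#' @param dataset a `simulated_dataset`.
#' @return a value in [0, 1]; a constant instrument returns 0 with a
#'   weak-instrument warning.
#' @export
instrument_relevance <- function(dataset) {
  if (stats::var(dataset$Z) < 1e-12) {
    warning("instrument is constant: no relevance (weak instrument)", call. = FALSE)
    return(0)
  }
  fit <- fit_logistic(cbind(Z = dataset$Z), dataset$T, warn_drop = FALSE)
  nagelkerke_r2(fit)
}

smd_across <- function(value, strata) {
  mu <- tapply(value, strata, mean)
  s <- stats::sd(value)
  if (!is.finite(s) || s < 1e-12) return(0)
  if (length(mu) < 2) return(0)
  max(abs(outer(mu, mu, `-`))) / s
}

#' Covariate balance by instrument versus by treatment
#'
#' For each level of the covariate (quartile bins for numeric covariates),
#' summarises the distribution of the instrument `Z` (n, median, quartiles)
#' and of treatment (mean).  The accompanying standardised mean differences
#' (largest pairwise difference in means across levels, divided by the
#' overall SD) quantify imbalance: a valid preference instrument should be
#' near-balanced across patient-level prognostic factors even when
#' treatment itself is strongly imbalanced.
#'
#' @param dataset a `simulated_dataset`.
#' @param covariate name of a covariate column in `dataset`.
#' @return a list with `by_level` (per-level summary `data.frame`),
#'   `smd_instrument` and `smd_treatment`.
#' @export
balance_by_instrument <- function(dataset, covariate) {
  if (!covariate %in% names(dataset))
    stop_usage("no covariate named '", covariate, "' in dataset")
  v <- dataset[[covariate]]
  strata <- if (is.numeric(v) && length(unique(v)) > 8) {
    br <- unique(stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
    cut(v, breaks = br, include.lowest = TRUE)
  } else {
    factor(v)
  }
  qs <- function(z) stats::quantile(z, c(0.25, 0.5, 0.75), names = FALSE)
  lev <- levels(strata)
  by_level <- do.call(rbind, lapply(lev, function(l) {
    z <- dataset$Z[strata == l]
    t <- dataset$T[strata == l]
    q <- if (length(z)) qs(z) else rep(NA_real_, 3)
    data.frame(level = l, n = length(z), z_q1 = q[1], z_median = q[2],
               z_q3 = q[3], t_mean = if (length(t)) mean(t) else NA_real_)
  }))
  list(by_level = by_level,
       smd_instrument = smd_across(dataset$Z, strata),
       smd_treatment = smd_across(as.numeric(dataset$T), strata))
}
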