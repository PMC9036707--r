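## Coefficient configuration for the two generating models and the
## pre-registered causal scenarios.
##
## Treatment model (binary logistic):
##   logit P(T = 1) = alpha + C * beta_CT + U * beta_UT + beta_hT * logit(p_h)
## where alpha is either alpha_T (preference off) or the centring constant
## that makes a hospital's expected treated proportion at average covariates
## equal its preference p_h (preference on, beta_hT = 1).
##
## Outcome model (cumulative logit over a 4-level ordinal outcome,
## category 1 = worst, death/vegetative combined):
##   logit P(Y <= k) = alpha_Y[k] + C * beta_CY + U * beta_UY
##                     + T * beta_T + beta_HY_scale * eta_h
## A negative beta_T lowers P(Y <= k), i.e. is beneficial; the default
## beta_T = -0.5 corresponds to a benefit odds ratio exp(0.5) = 1.65.

#' Generating-model coefficients
#'
#' Defaults are calibration choices, set so that (i) omitting the
#' unobserved confounders visibly biases covariate-adjusted estimates
#' (erasing most of the true effect) while (ii) hospital case-mix noise
#' stays small enough for the instrumental-variable strategies to recover
#' the effect when their assumptions hold; the severity gradients (worse
#' GCS motor, non-reactive pupils, higher CT class all increase both
#' treatment uptake and the odds of a poor outcome) encode confounding by
#' indication.  See the methods vignette for the calibration trade-off.
#' Vectors are named by design column (see [encode_design()]); reference
#' levels are GCS motor 1, both pupils reactive, CT class I.
#'
#' Sign conventions: positive outcome-model coefficients increase
#' `P(Y <= k)`, i.e. make the outcome worse.  GCS motor dummies are
#' negative (higher motor score = milder injury).  `beta_HY_scale`
#' multiplies the hospital performance draw `eta_h` in the outcome model;
#' the default -1 makes positive preference-performance correlation `rho`
#' correspond to better-performing hospitals treating more, so uncorrected
#' IV analysis overestimates the benefit.
#'
#' @param beta_CT,beta_UT named coefficient vectors of the observed /
#'   unobserved covariate blocks in the treatment model (log-odds).
#' @param beta_hT multiplier on `logit(p_h)` in the treatment model; the
#'   default 1 together with the centring constant calibrates each
#'   hospital's expected treated share to its preference.
#' @param alpha_T treatment-model intercept used when preference is off;
#'   default `qlogis(0.375)` targets the midpoint of the 17-58% preference
#'   range.
#' @param beta_CY,beta_UY named coefficient vectors of the outcome model
#'   (log-odds per cumulative-logit).
#' @param beta_T true treatment effect on the outcome log-odds; default
#'   -0.5 (odds ratio 1.65 in the beneficial direction).
#' @param beta_HY_scale multiplier on the hospital performance effect in
#'   the outcome model.
#' @param alpha_Y three strictly increasing cut-points of the 4-level
#'   outcome; the default gives a 40/15/20/25 split at average covariates.
#' @return an object of class `coefficient_config`.
#' @export
coefficient_config <- function(
    beta_CT = c(age_z = 0.17, sex = -0.04,
                gcs_motor2 = -0.14, gcs_motor3 = -0.29, gcs_motor4 = -0.40,
                gcs_motor5 = -0.50, gcs_motor6 = -0.61),
    beta_UT = c(pupils_one = 0.77, pupils_none = 1.66, sah = 0.66,
                ct_class_II = 0.33, ct_class_III = 0.77, ct_class_IV = 0.55,
                ct_class_V = 1.33, ct_class_VI = 1.66),
    beta_hT = 1,
    alpha_T = stats::qlogis(0.375),
    beta_CY = c(age_z = 0.22, sex = -0.05,
                gcs_motor2 = -0.19, gcs_motor3 = -0.38, gcs_motor4 = -0.53,
                gcs_motor5 = -0.67, gcs_motor6 = -0.82),
    beta_UY = c(pupils_one = 0.37, pupils_none = 0.80, sah = 0.32,
                ct_class_II = 0.16, ct_class_III = 0.37, ct_class_IV = 0.27,
                ct_class_V = 0.64, ct_class_VI = 0.80),
    beta_T = -0.5,
    beta_HY_scale = -1,
    alpha_Y = stats::qlogis(c(0.40, 0.55, 0.75))) {
  cfg <- list(beta_CT = beta_CT, beta_UT = beta_UT, beta_hT = beta_hT,
              alpha_T = alpha_T, beta_CY = beta_CY, beta_UY = beta_UY,
              beta_T = beta_T, beta_HY_scale = beta_HY_scale, alpha_Y = alpha_Y)
  class(cfg) <- "coefficient_config"
  validate_coefficients(cfg)
  cfg
}

validate_coefficients <- function(cfg) {
  if (length(cfg$alpha_Y) != 3 || any(diff(cfg$alpha_Y) <= 0))
    stop_config("alpha_Y must be three strictly increasing cut-points")
  for (nm in c("beta_hT", "alpha_T", "beta_T", "beta_HY_scale")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || !is.finite(cfg[[nm]]))
      stop_config(nm, " must be a single finite number")
  }
  for (nm in c("beta_CT", "beta_UT", "beta_CY", "beta_UY")) {
    v <- cfg[[nm]]
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      stop_config(nm, " must be a named vector (names = design columns)")
  }
  invisible(cfg)
}

## Align a named coefficient vector with the columns of a design block.
match_coefs <- function(beta, design, what) {
  if (!length(beta)) return(numeric(ncol(design)))
  missing <- setdiff(names(beta), colnames(design))
  if (length(missing))
    stop_config(what, " names not in design: ", paste(missing, collapse = ", "))
  out <- stats::setNames(numeric(ncol(design)), colnames(design))
  out[names(beta)] <- beta
  out
}

#' A causal scenario: which arrows of the data-generating DAG are active
#'
#' @param id scenario id (1-7 for the registry, any integer for custom
#'   scenarios).
#' @param treatment_effect_on is there a treatment effect (`beta_T`) on the
#'   outcome?
#' @param measured_confounding_on do the observed covariates affect
#'   treatment (`beta_CT`)?  Covariates always affect the outcome; the
#'   scenario switches only toggle arrows into treatment, which is what
#'   turns a prognostic factor into a confounder.
#' @param unmeasured_confounding_on do the unobserved covariates affect
#'   treatment (`beta_UT`)?
#' @param preference_on does hospital preference drive treatment
#'   (`beta_hT`)?  Off means treatment is assigned without any hospital
#'   signal and the instrument is pure noise.
#' @param common_cause_rho correlation between preference and hospital
#'   performance; non-zero activates the performance effect on the outcome
#'   (the exchangeability violation).
#' @param label short description.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, treatment_effect_on, measured_confounding_on,
                          unmeasured_confounding_on, preference_on,
                          common_cause_rho = 0, label = "") {
  s <- list(id = as.integer(id),
            treatment_effect_on = isTRUE(treatment_effect_on),
            measured_confounding_on = isTRUE(measured_confounding_on),
            unmeasured_confounding_on = isTRUE(unmeasured_confounding_on),
            preference_on = isTRUE(preference_on),
            common_cause_rho = common_cause_rho,
            label = label)
  if (abs(s$common_cause_rho) > 1) stop_config("|common_cause_rho| must be <= 1")
  class(s) <- "scenario_spec"
  s
}

#' The seven pre-registered scenarios
#'
#' Scenarios build up in complexity: (1) null, no treatment effect;
#' (2) RCT, randomly assigned treatment; (3) measured confounding only;
#' (4) measured confounding plus hospital preference; (5) measured and
#' unmeasured confounding; (6) as 5 plus preference; (7) as 6 plus a
#' common cause of preference and outcome (correlated hospital
#' performance, default rho = 0.3).  Scenarios 1-6 force the hospital
#' performance effect to zero.
#'
#' @param rho common-cause correlation used for scenario 7.
#' @return a list of seven [scenario_spec()] objects, indexed by id.
#' @export
scenario_registry <- function(rho = 0.3) {
  list(
    scenario_spec(1, FALSE, FALSE, FALSE, FALSE, 0, "null: no treatment effect"),
    scenario_spec(2, TRUE, FALSE, FALSE, FALSE, 0, "RCT: treatment randomly assigned"),
    scenario_spec(3, TRUE, TRUE, FALSE, FALSE, 0, "measured confounding"),
    scenario_spec(4, TRUE, TRUE, FALSE, TRUE, 0, "measured confounding + preference"),
    scenario_spec(5, TRUE, TRUE, TRUE, FALSE, 0, "measured + unmeasured confounding"),
    scenario_spec(6, TRUE, TRUE, TRUE, TRUE, 0, "unmeasured confounding + preference"),
    scenario_spec(7, TRUE, TRUE, TRUE, TRUE, rho,
                  "unmeasured confounding + preference + common cause")
  )
}

## Zero out coefficient blocks according to the scenario switches.
apply_scenario <- function(coefs, scenario) {
  out <- coefs
  if (!scenario$treatment_effect_on) out$beta_T <- 0
  if (!scenario$measured_confounding_on) out$beta_CT[] <- 0
  if (!scenario$unmeasured_confounding_on) out$beta_UT[] <- 0
  if (!scenario$preference_on) out$beta_hT <- 0
  out
}
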