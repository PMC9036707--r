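## Generation steps: Bernoulli treatment assignment from covariates and
## hospital preference, proportional-odds ordinal outcome, and the
## instrument (proportion treated per hospital).

covariate_lp <- function(cov, beta_obs, beta_unobs, marginals = attr(cov, "marginals")) {
  Xo <- encode_design(cov, "observed", marginals)
  Xu <- encode_design(cov, "unobserved", marginals)
  bo <- match_coefs(beta_obs, Xo, "observed coefficients")
  bu <- match_coefs(beta_unobs, Xu, "unobserved coefficients")
  mu <- expected_design_means(marginals)
  lp <- drop(Xo %*% bo + Xu %*% bu)
  center <- sum(mu[colnames(Xo)] * bo) + sum(mu[colnames(Xu)] * bu)
  lp - center
}

#' Assign treatment from covariates and hospital preference
#'
#' Draws `T_i ~ Bernoulli(expit(a_i + C_i beta_CT + U_i beta_UT))` where the
#' covariate linear predictor is centred at its population expectation under
#' the marginals and, with preference on, `a_i = beta_hT * logit(p_h(i))`.
#' With `beta_hT = 1` this offset-style entry calibrates each hospital: at
#' average covariates its expected treated proportion equals its preference
#' `p_h`, so the instrument lives on an interpretable probability scale and
#' the IV coefficient is directly comparable to `beta_T`.  With preference
#' off (or zeroed by the scenario) `a_i = alpha_T`.
#'
#' @param cov a `covariate_table`.
#' @param hosp_ids integer vector of hospital ids, one per patient.
#' @param hospitals a `hospital_table`.
#' @param coefs a [coefficient_config()].
#' @param scenario a [scenario_spec()]; its switches zero the relevant
#'   coefficient blocks (RCT/null: `beta_CT = beta_UT = beta_hT = 0`).
#' @param seed integer seed or `NULL`.
#' @return integer 0/1 treatment vector.
#' @export
assign_treatment <- function(cov, hosp_ids, hospitals, coefs = coefficient_config(),
                             scenario = scenario_registry()[[6]], seed = NULL) {
  coefs <- apply_scenario(coefs, scenario)
  lp <- covariate_lp(cov, coefs$beta_CT, coefs$beta_UT)
  a <- if (coefs$beta_hT != 0) {
    p <- hospitals$preference[match(hosp_ids, hospitals$hospital_id)]
    coefs$beta_hT * stats::qlogis(p)
  } else {
    coefs$alpha_T
  }
  pr <- stats::plogis(a + lp)
  with_seed(seed, as.integer(stats::runif(length(pr)) < pr))
}

#' Generate the 4-level ordinal outcome
#'
#' Draws `Y` from the cumulative-logit (proportional-odds) model
#' `logit P(Y <= k) = alpha_Y[k] + C beta_CY + U beta_UY + T beta_T +
#' beta_HY_scale * eta_h`, `k = 1..3`, with category 1 the worst outcome
#' (death/vegetative combined) and 4 the best.  A negative `beta_T` lowers
#' every `P(Y <= k)`, i.e. is beneficial, and by construction the cumulative
#' odds ratio between two patients differing only in treatment equals
#' `exp(beta_T)` at every cut.  The covariate linear predictor is centred at
#' its population expectation so the cut-points keep their configured
#' marginal interpretation.
#'
#' @inheritParams assign_treatment
#' @param treat integer 0/1 treatment vector.
#' @return integer outcome vector with values in 1..4.
#' @export
generate_outcome <- function(cov, treat, hosp_ids, hospitals,
                             coefs = coefficient_config(),
                             scenario = scenario_registry()[[6]], seed = NULL) {
  coefs <- apply_scenario(coefs, scenario)
  validate_coefficients(coefs)
  lp <- covariate_lp(cov, coefs$beta_CY, coefs$beta_UY)
  eta <- hospitals$performance[match(hosp_ids, hospitals$hospital_id)]
  lp <- lp + treat * coefs$beta_T + coefs$beta_HY_scale * eta
  cum <- stats::plogis(outer(lp, coefs$alpha_Y, `+`))  # n x 3, P(Y <= k)
  with_seed(seed, {
    u <- stats::runif(length(lp))
    1L + rowSums(u > cum)
  })
}

#' Compute the instrument: proportion of treated patients per hospital
#'
#' @param treat integer 0/1 treatment vector.
#' @param hosp_ids hospital id per patient.
#' @param hospitals a `hospital_table` (needed for `"assigned"` mode).
#' @param mode `"empirical"` (default): the observed treated proportion in
#'   the patient's hospital, including the patient;
#'   `"assigned"`: the hospital's latent preference `p_h`;
#'   `"leave_one_out"`: the treated proportion excluding the patient
#'   (requires >= 2 patients per hospital).
#' @return numeric instrument vector `Z`, constant within hospital in the
#'   first two modes.
#' @export
compute_instrument <- function(treat, hosp_ids, hospitals = NULL,
                               mode = c("empirical", "assigned", "leave_one_out")) {
  mode <- match.arg(mode)
  if (mode == "assigned") {
    if (is.null(hospitals)) stop_usage("'assigned' mode needs the hospital table")
    return(hospitals$preference[match(hosp_ids, hospitals$hospital_id)])
  }
  counts <- tapply(rep(1L, length(treat)), hosp_ids, sum)
  if (any(is.na(counts)) || !length(counts)) stop_usage("empty hospital in instrument computation")
  sums <- tapply(treat, hosp_ids, sum)
  key <- as.character(hosp_ids)
  n_h <- as.numeric(counts[key])
  s_h <- as.numeric(sums[key])
  if (mode == "empirical") return(s_h / n_h)
  if (any(counts < 2))
    stop_usage("leave-one-out instrument needs >= 2 patients in every hospital")
  (s_h - treat) / (n_h - 1)
}

#' Simulate one complete hospital-clustered dataset
#'
#' Runs the full generation pipeline: covariates, hospitals, patient
#' assignment, treatment, ordinal outcome and instrument.  For scenarios
#' without a common cause (`common_cause_rho == 0`) the hospital
#' performance effect is forced off (`performance_sd = 0`); scenario 7
#' draws preference and performance from the Gaussian copula at the
#' scenario's rho.  Sub-seeds for each stochastic step are derived
#' deterministically from `seed` via [derive_seed()].
#'
#' @param scenario a [scenario_spec()].
#' @param marginals a [covariate_marginals()].
#' @param hconfig a [hospital_config()]; its `rho` and (for scenarios 1-6)
#'   `performance_sd` are overridden by the scenario.
#' @param coefs a [coefficient_config()].
#' @param seed integer seed or `NULL`.
#' @param assignment `"balanced"` or `"random"` patient-to-hospital
#'   assignment.
#' @param instrument_mode passed to [compute_instrument()].
#' @return a `data.frame` of class `simulated_dataset`: covariate columns
#'   plus `hospital_id`, `Z`, `T`, `Y`; the realised `hospital_table` is
#'   attached as attribute `"hospitals"`.
#' @examples
#' d <- simulate_dataset(scenario_registry()[[2]],
#'                       hconfig = hospital_config(10, 30), seed = 1)
#' table(d$Y)
#' @export
simulate_dataset <- function(scenario = scenario_registry()[[6]],
                             marginals = covariate_marginals(),
                             hconfig = hospital_config(),
                             coefs = coefficient_config(),
                             seed = NULL,
                             assignment = c("balanced", "random"),
                             instrument_mode = "empirical") {
  assignment <- match.arg(assignment)
  hconfig$rho <- scenario$common_cause_rho
  if (scenario$common_cause_rho == 0) hconfig$performance_sd <- 0
  n <- hconfig$n_hospitals * hconfig$patients_per_hospital
  sub <- function(k) if (is.null(seed)) NULL else derive_seed(seed, rep = k)
  cov <- generate_covariates(n, marginals, seed = sub(1))
  hospitals <- draw_hospitals(hconfig, seed = sub(2))
  ids <- assign_patients(n, hconfig, seed = sub(3), mode = assignment)
  treat <- assign_treatment(cov, ids, hospitals, coefs, scenario, seed = sub(4))
  y <- generate_outcome(cov, treat, ids, hospitals, coefs, scenario, seed = sub(5))
  z <- compute_instrument(treat, ids, hospitals, mode = instrument_mode)
  out <- cbind(as.data.frame(cov),
               data.frame(hospital_id = ids, Z = z, T = treat, Y = y))
  attr(out, "marginals") <- marginals
  attr(out, "hospitals") <- hospitals
  attr(out, "scenario") <- scenario
  class(out) <- c("simulated_dataset", "data.frame")
  out
}
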