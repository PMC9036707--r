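## Hospital-level data generation: treatment preference (the instrument's
## source) and overall performance (the potential common cause), with a
## controlled Pearson correlation between the two.

#' Hospital-level simulation settings
#'
#' @param n_hospitals number of hospitals.
#' @param patients_per_hospital patients per hospital in balanced
#'   assignment; the default study size is 100 hospitals of 150 patients
#'   (15,000 patients).
#' @param pref_low,pref_high range of the hospital treatment preference
#'   (proportion of patients a hospital would treat); default 0.17-0.58,
#'   the observed between-hospital range of intracranial-pressure-monitor
#'   use.  Setting `pref_low == pref_high` collapses the instrument to a
#'   constant (a deliberate weak-instrument stress case).
#' @param performance_sd standard deviation of the hospital performance
#'   effect on the outcome log-odds scale; 0 switches the performance
#'   effect off entirely.
#' @param rho target Pearson correlation between preference and
#'   performance (the common cause of instrument and outcome).
#' @return an object of class `hospital_config`.
#' @export
hospital_config <- function(n_hospitals = 100, patients_per_hospital = 150,
                            pref_low = 0.17, pref_high = 0.58,
                            performance_sd = 0.3, rho = 0) {
  cfg <- list(n_hospitals = as.integer(n_hospitals),
              patients_per_hospital = as.integer(patients_per_hospital),
              pref_low = pref_low, pref_high = pref_high,
              performance_sd = performance_sd, rho = rho)
  class(cfg) <- "hospital_config"
  validate_hospital_config(cfg)
  cfg
}

## Pearson correlation between a uniform and a normal margin produced by a
## Gaussian copula with latent correlation r is r * sqrt(3 / pi); the latent
## correlation is therefore inflated by sqrt(pi / 3) to hit the target, and
## the attainable Pearson range is |rho| <= sqrt(3 / pi) ~ 0.977.
UNIF_NORMAL_ATTENUATION <- sqrt(3 / pi)

validate_hospital_config <- function(cfg) {
  if (cfg$n_hospitals < 1) stop_config("n_hospitals must be >= 1")
  if (cfg$patients_per_hospital < 1) stop_config("patients_per_hospital must be >= 1")
  if (!(cfg$pref_low > 0 && cfg$pref_high < 1 && cfg$pref_low <= cfg$pref_high))
    stop_config("preference range must satisfy 0 < pref_low <= pref_high < 1")
  if (cfg$performance_sd < 0) stop_config("performance_sd must be >= 0")
  if (abs(cfg$rho) > 1) stop_config("|rho| must be <= 1")
  if (abs(cfg$rho) > UNIF_NORMAL_ATTENUATION + 1e-12)
    stop_config("|rho| <= sqrt(3/pi) ~ 0.977 is the attainable Pearson ",
                "correlation between a uniform preference and a normal ",
                "performance margin")
  if (cfg$rho != 0 && cfg$performance_sd == 0)
    stop_config("cannot correlate preference with a degenerate (sd = 0) ",
                "performance effect")
  if (cfg$rho != 0 && cfg$pref_low == cfg$pref_high)
    stop_config("cannot correlate a constant preference with performance")
  invisible(cfg)
}

#' Draw hospitals with correlated preference and performance
#'
#' Preference and performance are generated from a Gaussian copula: a
#' bivariate standard normal pair with latent correlation
#' `rho * sqrt(pi/3)`, mapped to Uniform(`pref_low`, `pref_high`) by the
#' probability-integral transform (preference) and scaled by
#' `performance_sd` (performance).  The sqrt(pi/3) inflation exactly
#' compensates the attenuation of Pearson correlation under the
#' uniform-margin transform, so the expected Pearson correlation of the
#' returned pairs equals `rho`; the expected Spearman correlation is
#' `(6/pi) * asin(rho * sqrt(pi/3) / 2)`.
#'
#' @param config a [hospital_config()].
#' @param seed integer seed or `NULL`.
#' @return a `data.frame` of class `hospital_table` with columns
#'   `hospital_id`, `preference` (proportion) and `performance` (log-odds
#'   shift on the outcome scale); `config` is attached as an attribute.
#' @export
draw_hospitals <- function(config = hospital_config(), seed = NULL) {
  validate_hospital_config(config)
  n <- config$n_hospitals
  tab <- with_seed(seed, {
    z1 <- stats::rnorm(n)
    r <- config$rho / UNIF_NORMAL_ATTENUATION
    r <- max(-1, min(1, r))
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
    data.frame(
      hospital_id = seq_len(n),
      preference = config$pref_low + (config$pref_high - config$pref_low) * stats::pnorm(z1),
      performance = config$performance_sd * z2
    )
  })
  attr(tab, "config") <- config
  class(tab) <- c("hospital_table", "data.frame")
  tab
}

#' Assign patients to hospitals
#'
#' @param n_patients number of patients.
#' @param config a [hospital_config()].
#' @param seed integer seed or `NULL`.
#' @param mode `"balanced"` (default) gives every hospital exactly
#'   `n_patients / n_hospitals` patients in a random order and requires
#'   divisibility; `"random"` assigns each patient uniformly at random
#'   (multinomial counts).
#' @return an integer vector of hospital ids, one per patient.
#' @export
assign_patients <- function(n_patients, config = hospital_config(), seed = NULL,
                            mode = c("balanced", "random")) {
  mode <- match.arg(mode)
  validate_hospital_config(config)
  n_h <- config$n_hospitals
  if (mode == "balanced") {
    if (n_patients %% n_h != 0)
      stop_usage("balanced assignment needs n_patients (", n_patients,
                 ") divisible by n_hospitals (", n_h, ")")
    ids <- rep(seq_len(n_h), each = n_patients / n_h)
    with_seed(seed, sample(ids))
  } else {
    with_seed(seed, sample.int(n_h, n_patients, replace = TRUE))
  }
}
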