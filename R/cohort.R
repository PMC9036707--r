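## Patient-level synthetic cohort: marginal specification, sampling,
## design-matrix encoding.  Six prognostic factors are modelled, split into
## an "observed" set (GCS motor score, age, sex) and a hypothetically
## "unobserved" set (pupillary reactivity, SAH, Marshall CT class) used to
## emulate unmeasured confounding.

GCS_LEVELS    <- as.character(1:6)
PUPILS_LEVELS <- c("both", "one", "none")
CT_LEVELS     <- c("I", "II", "III", "IV", "V", "VI")

#' Marginal distributions of the patient prognostic factors
#'
#' Specifies the covariate generator for an IMPACT-like severe traumatic
#' brain injury cohort.  Factors are drawn independently of one another;
#' joint dependence (e.g. age vs. CT class) is deliberately out of scope.
#' The defaults are calibration choices plausible for moderate-to-severe
#' TBI (right-skewed age, male majority, frequent SAH), not estimates from
#' any particular data set.
#'
#' @param age list describing a shifted log-normal age distribution:
#'   `shift` (years, lower bound of support), `meanlog`, `sdlog` (log-scale
#'   parameters of the log-normal part), and `center`/`scale` (years), the
#'   fixed standardisation constants applied before age enters any linear
#'   predictor.
#' @param sex_male_prob probability that a patient is male.
#' @param gcs_motor_probs probability vector over the 6 Glasgow Coma Scale
#'   motor score categories (1 = no response ... 6 = obeys commands).
#' @param pupils_probs probability vector over pupillary reactivity
#'   (both reactive, one reactive, none reactive).
#' @param sah_prob probability of traumatic subarachnoid haemorrhage.
#' @param ct_class_probs probability vector over Marshall CT classes I-VI.
#' @param gcs_coding `"categorical"` (default) enters GCS motor score as
#'   reference-coded dummies; `"linear"` enters the 1-6 score as a single
#'   numeric column.
#' @return an object of class `covariate_marginals`.
#' @examples
#' m <- covariate_marginals(sex_male_prob = 0.8)
#' tab <- generate_covariates(500, m, seed = 1)
#' mean(tab$sex)
#' @export
covariate_marginals <- function(age = list(shift = 14, meanlog = log(18), sdlog = 0.55,
                                           center = 35, scale = 12.5),
                                sex_male_prob = 0.75,
                                gcs_motor_probs = c(0.12, 0.10, 0.18, 0.25, 0.20, 0.15),
                                pupils_probs = c(both = 0.65, one = 0.15, none = 0.20),
                                sah_prob = 0.45,
                                ct_class_probs = c(I = 0.10, II = 0.30, III = 0.20,
                                                   IV = 0.05, V = 0.25, VI = 0.10),
                                gcs_coding = c("categorical", "linear")) {
  gcs_coding <- match.arg(gcs_coding)
  m <- list(age = age, sex_male_prob = sex_male_prob,
            gcs_motor_probs = unname(gcs_motor_probs),
            pupils_probs = unname(pupils_probs), sah_prob = sah_prob,
            ct_class_probs = unname(ct_class_probs), gcs_coding = gcs_coding)
  class(m) <- "covariate_marginals"
  validate_marginals(m)
  m
}

validate_marginals <- function(m) {
  check_probs <- function(p, k, what) {
    if (length(p) != k || anyNA(p) || any(p < 0) || any(p > 1))
      stop_config(what, " must be ", k, " probabilities in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
      stop_config(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  check_probs(m$gcs_motor_probs, 6, "gcs_motor_probs")
  check_probs(m$pupils_probs, 3, "pupils_probs")
  check_probs(m$ct_class_probs, 6, "ct_class_probs")
  for (nm in c("sex_male_prob", "sah_prob")) {
    p <- m[[nm]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      stop_config(nm, " must be a single probability in [0, 1]")
  }
  a <- m$age
  need <- c("shift", "meanlog", "sdlog", "center", "scale")
  if (!is.list(a) || !all(need %in% names(a)))
    stop_config("age must be a list with fields ", paste(need, collapse = ", "))
  if (a$shift < 0 || a$sdlog < 0 || a$scale <= 0)
    stop_config("age support must be positive: shift >= 0, sdlog >= 0, scale > 0")
  invisible(m)
}

#' Draw a synthetic patient covariate table
#'
#' Each row is one patient; the six prognostic factors are independent draws
#' from the configured marginals.  With the same `(n, marginals, seed)` the
#' result is identical across calls and platforms.
#'
#' @param n number of patients (may be 0, giving an empty table with the
#'   full schema).
#' @param marginals a [covariate_marginals()] object.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a `data.frame` of class `covariate_table` with columns `age`
#'   (years), `sex` (1 = male), `gcs_motor` (ordered factor 1-6), `pupils`
#'   (factor both/one/none), `sah` (0/1), `ct_class` (factor I-VI).  The
#'   marginals used are attached as attribute `"marginals"` so the encoding
#'   map travels with the table.
#' @export
generate_covariates <- function(n, marginals = covariate_marginals(), seed = NULL) {
  validate_marginals(marginals)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != round(n))
    stop_usage("n must be a single non-negative integer")
  n <- as.integer(n)
  tab <- with_seed(seed, {
    a <- marginals$age
    data.frame(
      age = a$shift + stats::rlnorm(n, a$meanlog, a$sdlog),
      sex = as.integer(stats::runif(n) < marginals$sex_male_prob),
      gcs_motor = factor(sample.int(6, n, replace = TRUE, prob = marginals$gcs_motor_probs),
                         levels = 1:6, labels = GCS_LEVELS, ordered = TRUE),
      pupils = factor(PUPILS_LEVELS[sample.int(3, n, replace = TRUE, prob = marginals$pupils_probs)],
                      levels = PUPILS_LEVELS),
      sah = as.integer(stats::runif(n) < marginals$sah_prob),
      ct_class = factor(CT_LEVELS[sample.int(6, n, replace = TRUE, prob = marginals$ct_class_probs)],
                        levels = CT_LEVELS)
    )
  })
  attr(tab, "marginals") <- marginals
  class(tab) <- c("covariate_table", "data.frame")
  tab
}

design_columns <- function(marginals, subset) {
  obs <- c("age_z", "sex",
           if (marginals$gcs_coding == "categorical") paste0("gcs_motor", 2:6) else "gcs_motor")
  unobs <- c(paste0("pupils_", PUPILS_LEVELS[-1]), "sah", paste0("ct_class_", CT_LEVELS[-1]))
  switch(subset, observed = obs, unobserved = unobs, all = c(obs, unobs),
         stop_usage("unknown covariate subset '", subset,
                    "'; use 'observed', 'unobserved' or 'all'"))
}

#' Encode a covariate table as a numeric design block
#'
#' Deterministic encoding map: age is standardised with the configured
#' `center`/`scale`, binary factors stay 0/1, and the categorical factors
#' enter as reference-level dummies (first level = reference, so a patient
#' at all reference levels encodes to all-zero dummy columns).  The
#' observed/unobserved split follows the confounder partition: observed =
#' \{GCS motor, age, sex\}, unobserved = \{pupils, SAH, CT class\}.
#'
#' @param table a `covariate_table`.
#' @param subset `"observed"`, `"unobserved"` or `"all"`.
#' @param marginals the marginals carrying the encoding constants; defaults
#'   to those attached to `table`.
#' @return a numeric matrix with one row per patient and named columns.
#' @seealso [decode_design()] for the inverse map.
#' @export
encode_design <- function(table, subset = c("observed", "unobserved", "all"),
                          marginals = attr(table, "marginals")) {
  if (length(subset) == 1 && !subset %in% c("observed", "unobserved", "all"))
    stop_usage("unknown covariate subset '", subset,
               "'; use 'observed', 'unobserved' or 'all'")
  subset <- match.arg(subset)
  if (is.null(marginals)) marginals <- covariate_marginals()
  cols <- design_columns(marginals, subset)
  n <- nrow(table)
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  if ("age_z" %in% cols)
    out[, "age_z"] <- (table$age - marginals$age$center) / marginals$age$scale
  if ("sex" %in% cols) out[, "sex"] <- as.numeric(table$sex)
  if (marginals$gcs_coding == "categorical") {
    for (k in 2:6) {
      nm <- paste0("gcs_motor", k)
      if (nm %in% cols) out[, nm] <- as.numeric(table$gcs_motor == GCS_LEVELS[k])
    }
  } else if ("gcs_motor" %in% cols) {
    out[, "gcs_motor"] <- as.numeric(as.integer(table$gcs_motor))
  }
  for (lv in PUPILS_LEVELS[-1]) {
    nm <- paste0("pupils_", lv)
    if (nm %in% cols) out[, nm] <- as.numeric(table$pupils == lv)
  }
  if ("sah" %in% cols) out[, "sah"] <- as.numeric(table$sah)
  for (lv in CT_LEVELS[-1]) {
    nm <- paste0("ct_class_", lv)
    if (nm %in% cols) out[, nm] <- as.numeric(table$ct_class == lv)
  }
  out
}

#' Invert the design encoding back to covariate values
#'
#' Recovers the original covariate table from a full (`subset = "all"`)
#' design block produced by [encode_design()].  Age is de-standardised with
#' the same constants; dummy blocks are mapped back to factor levels.
#'
#' @param design numeric matrix from `encode_design(..., subset = "all")`.
#' @param marginals the marginals holding the encoding constants.
#' @return a `covariate_table`.
#' @export
decode_design <- function(design, marginals = covariate_marginals()) {
  cols <- design_columns(marginals, "all")
  if (!all(cols %in% colnames(design)))
    stop_usage("design lacks columns: ",
               paste(setdiff(cols, colnames(design)), collapse = ", "))
  n <- nrow(design)
  from_dummies <- function(prefix, levels) {
    idx <- rep(1L, n)
    for (k in seq_along(levels)[-1]) {
      hit <- design[, paste0(prefix, levels[k])] == 1
      idx[hit] <- k
    }
    factor(levels[idx], levels = levels)
  }
  gcs <- if (marginals$gcs_coding == "categorical") {
    idx <- rep(1L, n)
    for (k in 2:6) idx[design[, paste0("gcs_motor", k)] == 1] <- k
    factor(GCS_LEVELS[idx], levels = GCS_LEVELS, ordered = TRUE)
  } else {
    factor(GCS_LEVELS[as.integer(design[, "gcs_motor"])], levels = GCS_LEVELS, ordered = TRUE)
  }
  tab <- data.frame(
    age = design[, "age_z"] * marginals$age$scale + marginals$age$center,
    sex = as.integer(design[, "sex"]),
    gcs_motor = gcs,
    pupils = from_dummies("pupils_", PUPILS_LEVELS),
    sah = as.integer(design[, "sah"]),
    ct_class = from_dummies("ct_class_", CT_LEVELS)
  )
  attr(tab, "marginals") <- marginals
  class(tab) <- c("covariate_table", "data.frame")
  tab
}

## Population expectation of every design column under the marginals, used
## to centre covariate linear predictors so intercepts/cut-points keep their
## configured interpretation regardless of coefficient settings.
expected_design_means <- function(marginals) {
  a <- marginals$age
  e_age <- a$shift + exp(a$meanlog + a$sdlog^2 / 2)
  obs <- c(age_z = (e_age - a$center) / a$scale, sex = marginals$sex_male_prob)
  obs <- c(obs, if (marginals$gcs_coding == "categorical") {
    stats::setNames(marginals$gcs_motor_probs[2:6], paste0("gcs_motor", 2:6))
  } else {
    c(gcs_motor = sum(1:6 * marginals$gcs_motor_probs))
  })
  unobs <- c(stats::setNames(marginals$pupils_probs[-1], paste0("pupils_", PUPILS_LEVELS[-1])),
             sah = marginals$sah_prob,
             stats::setNames(marginals$ct_class_probs[-1], paste0("ct_class_", CT_LEVELS[-1])))
  c(obs, unobs)
}
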