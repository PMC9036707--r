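# adjivsim

Simulation framework for studying **instrumental-variable (IV) analysis
with hospital treatment preference as the instrument**, and in particular
the "adjusted IV" variant that additionally conditions on the hospital to
absorb a common cause of instrument and outcome.

## The problem

In observational comparative-effectiveness research, confounding by
indication (sicker patients are treated more often) biases naive treatment
effect estimates, and covariate or propensity-score adjustment only fixes
what is measured. Between-hospital variation in treatment policy offers an
instrument: the proportion of treated patients in a hospital, *Z*, predicts
a patient's treatment but should be unrelated to individual prognosis. IV
analysis, however, assumes the instrument shares no common cause with the
outcome — dubious when hospitals that prefer a treatment also differ in
overall quality of care.

`adjivsim` generates hospital-clustered cohorts modelled on severe
traumatic brain injury with a 4-level ordinal outcome drawn from a
proportional-odds model

    logit P(Y <= k) = alpha_k + C*beta_CY + U*beta_UY + T*beta_T + eta_h,

a true treatment effect `beta_T = -0.5` (benefit odds ratio
`exp(0.5) = 1.65`), observed confounders `C` (GCS motor score, age, sex),
hypothetically unobserved confounders `U` (pupillary reactivity, SAH,
Marshall CT class), and hospital preference/performance pairs drawn from a
Gaussian copula with controlled Pearson correlation. Six estimation
strategies are compared across seven pre-registered causal scenarios:

| strategy | model | estimand |
|---|---|---|
| a | `Y ~ T` | treatment effect |
| b | `Y ~ C + T` | treatment effect |
| c | `Y ~ PS + T` | treatment effect |
| d | `Y ~ Z` | preference effect |
| e | `Y ~ Z + hospital` | preference effect (adjusted IV) |
| f | `Y ~ Z + hospital + C + U` | preference effect (full control model) |

All models are fitted by the package's own Newton–Raphson
proportional-odds/logistic maximum-likelihood engine with model-based
standard errors, a collinearity screen, and explicit non-convergence
flagging (see the methods vignette in `vignettes/adjusted-iv-methods.Rmd`).

## Worked example

```r
library(adjivsim)

# one dataset from scenario 6: measured + unmeasured confounding,
# active hospital preference (15,000 patients, 100 hospitals)
d <- simulate_dataset(scenario_registry()[[6]], seed = 1)
mean(d$T)                  # 0.383  (treated fraction)
instrument_relevance(d)    # 0.072  (Nagelkerke R2 of T ~ Z)

estimate_effect("b", d)    # beta = -0.141 (SE 0.031)  <- biased: U omitted
estimate_effect("d", d)    # beta = -0.463 (SE 0.131)  <- IV, near truth
estimate_effect("f", d)    # beta = -0.511 (SE 0.133)  <- full control model
```

With the truth at −0.5, covariate adjustment (b) loses most of the effect
because the unobserved confounders drive treatment, while the IV
strategies recover it at the price of a four-fold larger standard error.
A small Monte-Carlo study contrasts plain IV (d) and adjusted IV (e) once a
common cause links preference and hospital performance (scenario 7):

```r
cfg <- study_config(scenarios = c(6, 7), rho_values = 0.3,
                    strategies = c("b", "d", "e"), n_reps = 50, seed = 7)
res <- run_study(cfg)
res$summary
#   scenario rho strategy mean_beta mean_model_se empirical_sd
#          6 0.0        b     -0.16         0.031        0.032
#          6 0.0        d     -0.39         0.136        0.149
#          6 0.0        e     -0.39         0.136        0.149
#          7 0.3        b     -0.19         0.031        0.033
#          7 0.3        d     -1.13         0.137        0.349
#          7 0.3        e     -0.44         0.143        0.148
```

Without a common cause (scenario 6) both IV variants sit near the truth.
With preference–performance correlation 0.3, plain IV skews to −1.13 with
twice the spread, while adjusted IV stays at −0.44: conditioning on the
hospital absorbs the common cause. `run_study(cfg, out_dir = "results")`
additionally writes `summary.csv`, `estimates.csv`, a histogram export of
the d/e point estimates, and a run log; a thin command-line wrapper lives
at `inst/cli/adjiv.R`.

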