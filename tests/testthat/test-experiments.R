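test_that("the scenario registry encodes the pre-registered flag matrix", {
  reg <- scenario_registry()
  flags <- t(vapply(reg, function(s) {
    c(s$treatment_effect_on, s$measured_confounding_on,
      s$unmeasured_confounding_on, s$preference_on, s$common_cause_rho > 0)
  }, logical(5)))
  expected <- matrix(c(
    FALSE, FALSE, FALSE, FALSE, FALSE,  # 1 null
    TRUE,  FALSE, FALSE, FALSE, FALSE,  # 2 RCT
    TRUE,  TRUE,  FALSE, FALSE, FALSE,  # 3 measured confounding
    TRUE,  TRUE,  FALSE, TRUE,  FALSE,  # 4 + preference
    TRUE,  TRUE,  TRUE,  FALSE, FALSE,  # 5 + unmeasured confounding
    TRUE,  TRUE,  TRUE,  TRUE,  FALSE,  # 6 + preference
    TRUE,  TRUE,  TRUE,  TRUE,  TRUE    # 7 + common cause
  ), nrow = 7, byrow = TRUE)
  expect_identical(unname(flags), expected)
  expect_identical(vapply(reg, `[[`, integer(1), "id"), 1:7)
})

test_that("seed derivation is deterministic, in range, and collision-averse", {
  s1 <- derive_seed(42, 6, 0.3, 17)
  expect_identical(s1, derive_seed(42, 6, 0.3, 17))
  grid <- expand.grid(m = c(1, 42), s = 1:7, rho = c(0, 0.3, 0.5), r = 1:50)
  seeds <- mapply(derive_seed, grid$m, grid$s, grid$rho, grid$r)
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("replications are reproducible and scenario-correct", {
  cfg <- scaled_config(strategies = c("a", "d"), n_reps = 2, n_hospitals = 10)
  r1 <- run_replication(cfg, 6, 0, 3)
  r2 <- run_replication(cfg, 6, 0, 3)
  expect_identical(r1, r2)
  expect_identical(r1$strategy, c("a", "d"))
  expect_identical(r1$estimand, c("treatment_effect", "preference_effect"))
  # different replication index gives different data
  r3 <- run_replication(cfg, 6, 0, 4)
  expect_false(identical(r1$beta, r3$beta))
})

test_that("summaries are internally consistent and order-invariant", {
  cfg <- scaled_config(strategies = c("a", "b"), n_reps = 6, n_hospitals = 10)
  est <- do.call(rbind, lapply(1:6, function(k) run_replication(cfg, 2, 0, k)))
  s <- summarize_estimates(est)
  a_rows <- est[est$strategy == "a" & est$converged, ]
  expect_equal(s$mean_beta[s$strategy == "a"], mean(a_rows$beta), tolerance = 1e-12)
  expect_equal(s$empirical_sd[s$strategy == "a"], sd(a_rows$beta), tolerance = 1e-12)

  # permutation of rows leaves the summary unchanged
  set.seed(1)
  s2 <- summarize_estimates(est[sample(nrow(est)), ])
  expect_equal(s, s2)

  # single replication: empirical SD reported as NA
  s1 <- summarize_estimates(est[est$rep == 1, ])
  expect_true(all(is.na(s1$empirical_sd)))

  # hand-checkable toy table
  toy <- data.frame(scenario = 1, rho = 0, rep = 1:3, strategy = "a",
                    estimand = "treatment_effect", beta = c(1, 2, 3),
                    se = c(0.1, 0.2, 0.3), converged = TRUE)
  st <- summarize_estimates(toy)
  expect_equal(st$mean_beta, 2)
  expect_equal(st$mean_model_se, 0.2, tolerance = 1e-12)
  expect_equal(st$empirical_sd, 1, tolerance = 1e-12)
  expect_identical(st$n_reps, 3L)
})

test_that("run_study validates inputs and writes its exports", {
  expect_error(study_config(strategies = character()), class = "adjiv_config_error")
  expect_error(study_config(scenarios = 9), class = "adjiv_config_error")

  cfg <- study_config(scenarios = c(2, 7), rho_values = 0.3,
                      hospitals = hospital_config(10, 30),
                      strategies = c("a", "d", "e"), n_reps = 3, seed = 9)
  out_dir <- withr::local_tempdir()
  res <- run_study(cfg, out_dir = out_dir)
  expect_s3_class(res, "adjiv_study")
  expect_identical(sort(unique(res$estimates$scenario)), c(2L, 7L))
  expect_identical(nrow(res$estimates), 2L * 3L * 3L)
  expect_true(all(file.exists(file.path(out_dir,
    c("estimates.csv", "summary.csv", "histogram_d_e.csv", "run.log")))))
  back <- read.csv(file.path(out_dir, "summary.csv"))
  expect_equal(back$mean_beta, res$summary$mean_beta, tolerance = 1e-12)
  hist_back <- read.csv(file.path(out_dir, "histogram_d_e.csv"))
  expect_true(all(hist_back$strategy %in% c("d", "e")))
  # bin counts add up to the converged replications
  n_d7 <- sum(res$estimates$strategy == "d" & res$estimates$scenario == 7 &
                res$estimates$converged)
  expect_identical(sum(hist_back$count[hist_back$strategy == "d" &
                                         hist_back$scenario == 7]), n_d7)
})

test_that("parallel execution reproduces sequential results exactly", {
  cfg <- study_config(scenarios = 2, hospitals = hospital_config(5, 30),
                      strategies = c("a", "b"), n_reps = 4, seed = 77)
  seq_res <- run_study(cfg)
  par_res <- run_study(cfg, cores = 2)
  expect_identical(seq_res$estimates, par_res$estimates)
})

test_that("summary means are stable when the replication count grows", {
  # the scaled-down justification: means at R and 4R replications agree
  # within 3 Monte-Carlo standard errors
  cfg_small <- study_config(scenarios = 2, hospitals = hospital_config(5, 100),
                            strategies = "b", n_reps = 75, seed = 5150)
  cfg_large <- cfg_small
  cfg_large$n_reps <- 300L
  s_small <- mc_cell(cfg_small, 2)$summary
  s_large <- mc_cell(cfg_large, 2)$summary
  mcse <- s_large$empirical_sd / sqrt(s_small$n_reps)
  expect_lt(abs(s_small$mean_beta - s_large$mean_beta), 3 * mcse)
})

test_that("YAML round-trip reconstructs the configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "covariates:",
    "  sex_male_prob: 0.8",
    "hospitals:",
    "  n_hospitals: 12",
    "  patients_per_hospital: 50",
    "coefficients:",
    "  beta_T: -0.4",
    "study:",
    "  scenarios: [2, 6]",
    "  strategies: [a, b, f]",
    "  n_reps: 7",
    "  seed: 99"
  ), path)
  cfg <- read_study_config(path)
  expect_identical(cfg$hospitals$n_hospitals, 12L)
  expect_identical(cfg$marginals$sex_male_prob, 0.8)
  expect_identical(cfg$coefficients$beta_T, -0.4)
  expect_identical(cfg$scenarios, c(2L, 6L))
  expect_identical(cfg$strategies, c("a", "b", "f"))
  expect_identical(cfg$n_reps, 7L)
})
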