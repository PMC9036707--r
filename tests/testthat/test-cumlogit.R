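test_that("PO fitter matches a brute-force likelihood oracle on a grouped table", {
  # 2 x 4 grouped data: binary x, four outcome levels with fixed cell counts
  counts0 <- c(40, 25, 20, 15)  # x = 0
  counts1 <- c(20, 20, 25, 35)  # x = 1
  x <- matrix(rep(c(0, 1), times = c(sum(counts0), sum(counts1))), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1:4, counts0), rep(1:4, counts1))
  fit <- fit_proportional_odds(x, y)
  orc <- oracle_po_fit(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients["x"] - orc$beta), 1e-6)
  expect_lt(max(abs(fit$cutpoints - orc$cutpoints)), 1e-6)
  expect_lt(abs(fit$logLik - orc$logLik), 1e-6)
})

test_that("PO fitter agrees with the brute-force oracle on random small instances", {
  set.seed(99)
  n_match <- 0
  for (i in 1:20) {
    n <- sample(80:400, 1)
    p <- sample(1:4, 1)
    K <- sample(3:4, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    beta <- runif(p, -0.8, 0.8)
    cuts <- sort(qlogis((1:(K - 1)) / K)) + rnorm(K - 1, 0, 0.2)
    cuts <- sort(cuts)
    lp <- drop(X %*% beta)
    cum <- plogis(outer(lp, cuts, `+`))
    u <- runif(n)
    y <- 1L + rowSums(u > cum)
    if (length(unique(y)) < K) next
    fit <- fit_proportional_odds(X, y)
    orc <- oracle_po_fit(X, y)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$coefficients - orc$beta)), 1e-5)
    expect_lt(max(abs(fit$cutpoints - orc$cutpoints)), 1e-5)
    n_match <- n_match + 1
  }
  expect_gte(n_match, 18)
})

test_that("PO fitter agrees with an established independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(7)
  for (i in 1:8) {
    n <- 400
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
    lp <- 0.6 * X[, "a"] - 0.4 * X[, "b"]
    cum <- plogis(outer(lp, c(-0.8, 0.2, 1.1), `+`))
    y <- 1L + rowSums(runif(n) > cum)
    if (length(unique(y)) < 4) next
    fit <- fit_proportional_odds(X, y)
    pf <- MASS::polr(factor(y) ~ X, method = "logistic",
                     control = list(reltol = 1e-12))
    # polr parameterises logit P(Y <= k) = zeta_k - x'beta
    expect_lt(max(abs(fit$coefficients + coef(pf))), 1e-5)
    expect_lt(max(abs(fit$cutpoints - pf$zeta)), 1e-5)
  }
})

test_that("binary outcomes reduce the PO fit to the logistic fit", {
  set.seed(21)
  n <- 300
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- 1L + rbinom(n, 1, plogis(-0.3 + 0.7 * X[, 1]))
  po <- fit_proportional_odds(X, y)
  lg <- fit_logistic(X, as.numeric(y == 1))  # P(Y <= 1) = P(lower category)
  expect_lt(max(abs(po$coefficients - lg$coefficients[-1])), 1e-8)
  expect_lt(abs(po$cutpoints[1] - lg$coefficients["(Intercept)"]), 1e-8)
  expect_lt(abs(po$logLik - lg$logLik), 1e-8)
  expect_lt(max(abs(po$se - lg$se[-1])), 1e-7)
})

test_that("logistic fitter reproduces closed-form special cases", {
  # intercept-only: logit of the empirical proportion
  y <- rep(c(1, 0), c(30, 70))
  f0 <- fit_logistic(matrix(numeric(0), nrow = 100, ncol = 0), y)
  expect_equal(unname(f0$coefficients["(Intercept)"]), qlogis(0.3), tolerance = 1e-9)

  # 2 x 2 table: slope equals the log odds ratio of the table
  tab <- c(n00 = 40, n01 = 25, n10 = 20, n11 = 35)
  x <- rep(c(0, 0, 1, 1), tab)
  y <- rep(c(0, 1, 0, 1), tab)
  f <- fit_logistic(cbind(x = x), y)
  lor <- log((tab["n11"] * tab["n00"]) / (tab["n10"] * tab["n01"]))
  expect_equal(unname(f$coefficients["x"]), unname(lor), tolerance = 1e-8)

  # cross-check against glm on a random instance
  set.seed(5)
  X <- cbind(a = rnorm(200), b = runif(200))
  yy <- rbinom(200, 1, plogis(0.2 + 0.8 * X[, 1] - X[, 2]))
  fg <- glm(yy ~ X, family = binomial)
  fm <- fit_logistic(X, yy)
  expect_lt(max(abs(fm$coefficients - coef(fg))), 1e-7)
  expect_lt(max(abs(fm$se - summary(fg)$coefficients[, 2])), 1e-6)
})

test_that("complete separation is flagged as non-convergence", {
  x <- cbind(x = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  f <- suppressWarnings(fit_logistic(x, y))
  expect_false(f$converged)

  # separated ordinal outcome as well
  y_ord <- c(rep(1L, 20), rep(3L, 20))
  fp <- suppressWarnings(fit_proportional_odds(x, y_ord))
  expect_false(fp$converged)
})

test_that("null-model sanity: estimates stay within 4 SE of zero", {
  set.seed(31)
  n <- 50000
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  cum <- plogis(outer(numeric(n), qlogis(c(0.3, 0.6, 0.85)), `+`))
  y <- 1L + rowSums(runif(n) > cum)
  f <- fit_proportional_odds(X, y)
  expect_true(f$converged)
  expect_true(all(abs(f$coefficients) < 4 * f$se))
})

test_that("observed information matches a finite-difference Hessian", {
  set.seed(41)
  n <- 250
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  cum <- plogis(outer(0.5 * X[, 1], qlogis(c(0.3, 0.6, 0.85)), `+`))
  y <- 1L + rowSums(runif(n) > cum)
  fit <- fit_proportional_odds(X, y)
  par_hat <- c(fit$cutpoints, fit$coefficients)
  yi <- match(y, sort(unique(y)))
  f_ll <- function(par) {
    adjivsim:::polik_parts(par[1:3], par[4:5], X, yi, 4L, hess = FALSE)$ll
  }
  H_num <- numeric_hessian(f_ll, par_hat)
  H_ana <- adjivsim:::polik_parts(fit$cutpoints, fit$coefficients, X, yi, 4L)$hess
  expect_lt(max(abs(H_num - H_ana)) / max(abs(H_ana)), 1e-4)
  # SEs are the inverse observed information at the optimum
  expect_equal(unname(c(fit$se_cutpoints, fit$se)),
               unname(sqrt(diag(solve(-H_ana)))), tolerance = 1e-6)
})

test_that("standardising a column rescales beta and SE, not the z-statistic", {
  set.seed(51)
  n <- 400
  X <- cbind(a = rnorm(n, sd = 3), b = rbinom(n, 1, 0.5))
  cum <- plogis(outer(0.3 * X[, 1], qlogis(c(0.4, 0.7)), `+`))
  y <- 1L + rowSums(runif(n) > cum)
  f1 <- fit_proportional_odds(X, y)
  X2 <- X; X2[, "a"] <- X2[, "a"] / sd(X2[, "a"])
  f2 <- fit_proportional_odds(X2, y)
  sc <- sd(X[, "a"])
  expect_equal(unname(f2$coefficients["a"]), unname(f1$coefficients["a"] * sc),
               tolerance = 1e-6)
  expect_equal(unname(f2$se["a"]), unname(f1$se["a"] * sc), tolerance = 1e-5)
  expect_equal(unname(f2$coefficients["a"] / f2$se["a"]),
               unname(f1$coefficients["a"] / f1$se["a"]), tolerance = 1e-5)
})

test_that("collinearity screen drops offending columns with a warning", {
  set.seed(61)
  X <- cbind(a = rnorm(100), b = rnorm(100))
  X <- cbind(X, c = X[, "a"] + X[, "b"], d = 1)  # collinear + constant
  cum <- plogis(outer(0.2 * X[, 1], qlogis(c(0.4, 0.7)), `+`))
  y <- 1L + rowSums(runif(100) > cum)
  expect_warning(f <- fit_proportional_odds(X, y), "collinear")
  expect_setequal(f$dropped, c("c", "d"))
  expect_setequal(names(f$coefficients), c("a", "b"))
  expect_true(f$converged)
})

test_that("pseudo-R2 variants behave as documented", {
  set.seed(71)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * x))
  f1 <- fit_logistic(cbind(x = x), y)
  f0 <- fit_logistic(matrix(numeric(0), nrow = n, ncol = 0), y)

  # hand evaluation of the formulas
  cs <- 1 - exp(2 * (f1$null_logLik - f1$logLik) / n)
  expect_equal(pseudo_r2(f1, type = "cox_snell"), cs, tolerance = 1e-12)
  expect_equal(nagelkerke_r2(f1), cs / (1 - exp(2 * f1$null_logLik / n)),
               tolerance = 1e-12)
  expect_equal(pseudo_r2(f1, type = "mcfadden"), 1 - f1$logLik / f1$null_logLik,
               tolerance = 1e-12)

  # ll_model = ll_null -> 0; adding a predictor never lowers R2
  expect_equal(nagelkerke_r2(f0), 0, tolerance = 1e-9)
  X2 <- cbind(x = x, z = rnorm(n))
  f2 <- fit_logistic(X2, y)
  expect_gte(nagelkerke_r2(f2) + 1e-12, nagelkerke_r2(f1))
  expect_gt(nagelkerke_r2(f1), 0.1)
})

test_that("fit results serialise to JSON for logging", {
  y <- rep(c(1, 0), c(30, 70))
  f <- fit_logistic(cbind(x = rnorm(100)), y)
  j <- jsonlite::fromJSON(fit_json(f))
  expect_identical(j$model, "logistic")
  expect_true(is.logical(j$converged))
  expect_equal(j$logLik, f$logLik, tolerance = 1e-9)
})
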