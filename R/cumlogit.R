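## Self-contained maximum-likelihood fitting of the proportional-odds
## (cumulative-logit) model and binary logistic regression by
## Newton-Raphson with step-halving.  This is the numerical engine behind
## every estimation strategy; standard errors come from the inverse
## observed information at the optimum.
##
## Model and sign convention (matching the data generator):
##   logit P(Y <= k | x) = theta_k + x' beta,   k = 1..K-1,
## with theta strictly increasing and category 1 the worst outcome.  A
## binary y fitted as logit P(y = 1 | x) = a + x' b is the K = 2 special
## case with a = theta_1, b = beta.

## Drop design columns that are collinear (QR rank check at tol 1e-8),
## including columns collinear with the implicit intercept/cut-points.
screen_design <- function(x, tol = 1e-8, warn = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  if (ncol(x) == 0) return(list(x = x, dropped = character()))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  aug <- cbind(`(icpt)` = 1, x)
  qd <- qr(aug, tol = tol)
  keep_aug <- sort(qd$pivot[seq_len(qd$rank)])
  dropped <- setdiff(colnames(aug)[-1], colnames(aug)[keep_aug])
  if (length(dropped)) {
    if (warn)
      warning("dropping collinear design column(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, setdiff(colnames(x), dropped), drop = FALSE]
  }
  list(x = x, dropped = dropped)
}

## Log-likelihood, gradient and Hessian of the cumulative-logit model in
## natural parameters (theta, beta).  y is an integer vector in 1..K.
polik_parts <- function(theta, beta, x, y, K, hess = TRUE) {
  eta <- if (ncol(x)) drop(x %*% beta) else numeric(nrow(x))
  up <- y          # index of upper cut; K means +Inf
  lo <- y - 1L     # index of lower cut; 0 means -Inf
  A <- ifelse(up == K, Inf, theta[pmin(up, K - 1L)] + eta)
  B <- ifelse(lo == 0L, -Inf, theta[pmax(lo, 1L)] + eta)
  pA <- stats::plogis(A); pB <- stats::plogis(B)
  fA <- pA * (1 - pA);    fB <- pB * (1 - pB)
  P <- pmax(pA - pB, 1e-300)
  ll <- sum(log(P))
  g_eta <- (fA - fB) / P
  n_th <- K - 1L
  g_theta <- numeric(n_th)
  for (k in seq_len(n_th)) {
    g_theta[k] <- sum(fA[up == k] / P[up == k]) - sum(fB[lo == k] / P[lo == k])
  }
  g_beta <- if (ncol(x)) drop(crossprod(x, g_eta)) else numeric(0)
  out <- list(ll = ll, grad = c(g_theta, g_beta))
  if (!hess) return(out)
  fpA <- fA * (1 - 2 * pA); fpA[!is.finite(A)] <- 0
  fpB <- fB * (1 - 2 * pB); fpB[!is.finite(B)] <- 0
  w_ee <- (fpA - fpB) / P - g_eta^2
  p <- ncol(x)
  H <- matrix(0, n_th + p, n_th + p)
  ## theta-theta and theta-eta weights
  w_et <- matrix(0, nrow(x), n_th)
  for (k in seq_len(n_th)) {
    iu <- up == k; il <- lo == k
    H[k, k] <- sum(fpA[iu] / P[iu] - (fA[iu] / P[iu])^2) +
               sum(-fpB[il] / P[il] - (fB[il] / P[il])^2)
    if (k > 1) {
      ib <- up == k & lo == (k - 1L)  # observations straddling both cuts
      H[k, k - 1] <- H[k - 1, k] <- sum(fA[ib] * fB[ib] / P[ib]^2)
    }
    w_et[iu, k] <- fpA[iu] / P[iu] - fA[iu] * (fA[iu] - fB[iu]) / P[iu]^2
    w_et[il, k] <- w_et[il, k] - fpB[il] / P[il] + fB[il] * (fA[il] - fB[il]) / P[il]^2
  }
  if (p) {
    H[seq_len(n_th), n_th + seq_len(p)] <- t(crossprod(x, w_et))
    H[n_th + seq_len(p), seq_len(n_th)] <- crossprod(x, w_et)
    H[n_th + seq_len(p), n_th + seq_len(p)] <- crossprod(x, x * w_ee)
  }
  out$hess <- H
  out
}

new_fit <- function(model, coefficients, cutpoints, se, se_cutpoints, vcov,
                    logLik, null_logLik, converged, iterations, n, levels,
                    dropped) {
  structure(list(model = model, coefficients = coefficients,
                 cutpoints = cutpoints, se = se, se_cutpoints = se_cutpoints,
                 vcov = vcov, logLik = logLik, null_logLik = null_logLik,
                 converged = converged, iterations = iterations, n = n,
                 levels = levels, dropped = dropped),
            class = "adjiv_fit")
}

#' Fit a proportional-odds cumulative-logit model by maximum likelihood
#'
#' Newton-Raphson with step-halving on the parameterisation (first
#' cut-point, log increments between cut-points, slopes), which enforces
#' strictly increasing cut-points throughout the optimisation.  The model
#' is `logit P(Y <= k | x) = theta_k + x' beta`, so the reported slope for
#' a generating covariate matches the generator's coefficient sign (note
#' this is the negative of the `MASS::polr` convention).  Convergence
#' requires a relative log-likelihood change below `tol`, a maximum
#' absolute score below 1e-6 and a negligible final Newton step;
#' non-convergence (including complete separation, where estimates drift
#' without bound) is flagged, never silently reported as converged.
#' Standard errors are square roots of the diagonal of the inverse observed
#' information at the optimum, in natural (cut-point, slope) parameters.
#'
#' @param x numeric design matrix (no intercept column; the cut-points play
#'   that role).  Collinear columns, including columns constant in the
#'   sample, are dropped with a warning (`warn_drop = FALSE` silences it;
#'   dropped names are always recorded in the result).
#' @param y ordinal outcome: integer or factor with at least 2 observed
#'   levels; internally mapped to 1..K in increasing order.
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   tolerance.
#' @param warn_drop warn when the collinearity screen drops columns.
#' @return an object of class `adjiv_fit` with elements `coefficients`,
#'   `cutpoints`, `se`, `se_cutpoints`, `vcov` (natural parameters,
#'   cut-points first), `logLik`, `null_logLik` (cut-points-only model,
#'   closed form), `converged`, `iterations`, `n`, `levels`, `dropped`.
#' @examples
#' d <- simulate_dataset(scenario_registry()[[2]],
#'                       hconfig = hospital_config(10, 50), seed = 1)
#' fit <- fit_proportional_odds(cbind(T = d$T), d$Y)
#' coef(fit)
#' @export
fit_proportional_odds <- function(x, y, max_iter = 100, tol = 1e-10,
                                  warn_drop = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  lev <- sort(unique(as.vector(if (is.factor(y)) as.integer(y) else y)))
  K <- length(lev)
  if (K < 2) stop_usage("y must have at least 2 observed categories")
  yi <- match(if (is.factor(y)) as.integer(y) else y, lev)
  if (nrow(x) != length(yi)) stop_usage("nrow(x) must equal length(y)")
  sc <- screen_design(x, warn = warn_drop)
  x <- sc$x
  p <- ncol(x)
  n_th <- K - 1L

  ## start: empirical cumulative logits, zero slopes
  cum <- cumsum(tabulate(yi, K))[seq_len(n_th)] / length(yi)
  cum <- pmin(pmax(cum, 1e-6), 1 - 1e-6)
  theta <- stats::qlogis(cum)
  if (any(diff(theta) <= 0)) theta <- stats::qlogis((seq_len(n_th)) / K)
  psi <- c(theta[1], if (n_th > 1) log(diff(theta)), numeric(p))

  to_theta <- function(psi) {
    if (n_th == 1) psi[1] else cumsum(c(psi[1], exp(psi[2:n_th])))
  }
  eval_psi <- function(psi, hess = TRUE) {
    theta <- to_theta(psi)
    beta <- psi[n_th + seq_len(p)]
    parts <- polik_parts(theta, beta, x, yi, K, hess = hess)
    ## chain rule to psi space
    J <- diag(n_th + p)
    if (n_th > 1) {
      for (k in 2:n_th) J[k, 2:k] <- exp(psi[2:k])
      J[2:n_th, 1] <- 1
    }
    g_psi <- drop(crossprod(J, parts$grad))
    out <- list(ll = parts$ll, grad = parts$grad, g_psi = g_psi, theta = theta,
                beta = beta)
    if (hess) {
      Hp <- crossprod(J, parts$hess %*% J)
      if (n_th > 1) {
        for (j in 2:n_th)
          Hp[j, j] <- Hp[j, j] + sum(parts$grad[j:n_th]) * exp(psi[j])
      }
      out$hess_psi <- Hp
      out$hess_nat <- parts$hess
    }
    out
  }

  cur <- eval_psi(psi)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$hess_psi, cur$g_psi), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    ok <- FALSE
    for (h in 1:30) {
      cand <- psi - lambda * step
      ev <- eval_psi(cand, hess = FALSE)
      if (is.finite(ev$ll) && ev$ll >= cur$ll - 1e-12) { ok <- TRUE; break }
      lambda <- lambda / 2
    }
    if (!ok) break
    rel <- abs(ev$ll - cur$ll) / (abs(cur$ll) + 1e-10)
    psi <- cand
    cur <- eval_psi(psi)
    if (any(abs(cur$beta) > 1e4)) break  # divergence (e.g. separation)
    if (rel < tol && max(abs(cur$grad)) < 1e-6 &&
        max(abs(lambda * step)) < 1e-3) { converged <- TRUE; break }
  }

  nat_names <- c(paste0("cut", seq_len(n_th)), colnames(x))
  vcov <- matrix(NA_real_, n_th + p, n_th + p, dimnames = list(nat_names, nat_names))
  se_all <- rep(NA_real_, n_th + p)
  if (converged) {
    vc <- tryCatch(solve(-cur$hess_nat), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      dimnames(vc) <- list(nat_names, nat_names)
      vcov <- vc
      se_all <- sqrt(diag(vc))
    } else {
      converged <- FALSE
    }
  }
  counts <- tabulate(yi, K)
  ll_null <- sum(counts * log(counts / length(yi)))
  new_fit("cumulative_logit",
          coefficients = stats::setNames(cur$beta, colnames(x)),
          cutpoints = stats::setNames(cur$theta, paste0("cut", seq_len(n_th))),
          se = stats::setNames(se_all[n_th + seq_len(p)], colnames(x)),
          se_cutpoints = stats::setNames(se_all[seq_len(n_th)], paste0("cut", seq_len(n_th))),
          vcov = vcov, logLik = cur$ll, null_logLik = ll_null,
          converged = converged, iterations = iter, n = length(yi),
          levels = lev, dropped = sc$dropped)
}

#' Fit a binary logistic regression by maximum likelihood
#'
#' Newton-Raphson with step-halving for
#' `logit P(y = 1 | x) = a + x' b`, with an intercept added automatically.
#' Convergence and standard errors as in [fit_proportional_odds()]; with a
#' two-category ordinal outcome coded as the indicator of the lower
#' category, both fitters maximise the same likelihood and agree to
#' numerical precision.
#'
#' @param x numeric design matrix (intercept added internally).
#' @param y binary 0/1 response.
#' @inheritParams fit_proportional_odds
#' @return an `adjiv_fit`; `coefficients` starts with `"(Intercept)"`, and
#'   `null_logLik` is the closed-form intercept-only log-likelihood.
#' @export
fit_logistic <- function(x, y, max_iter = 100, tol = 1e-10, warn_drop = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_usage("y must be binary 0/1")
  if (nrow(x) != length(y)) stop_usage("nrow(x) must equal length(y)")
  if (length(unique(y)) < 2) stop_usage("y must have both classes present")
  sc <- screen_design(x, warn = warn_drop)
  X <- cbind(`(Intercept)` = 1, sc$x)
  p <- ncol(X)
  beta <- numeric(p)
  ll_of <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  cur_ll <- ll_of(beta)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  repeat {
    if (iter >= max_iter) break
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    H <- -crossprod(X, X * w)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    ok <- FALSE
    for (h in 1:30) {
      cand <- beta + lambda * step
      ll <- ll_of(cand)
      if (is.finite(ll) && ll >= cur_ll - 1e-12) { ok <- TRUE; break }
      lambda <- lambda / 2
    }
    if (!ok) break
    rel <- abs(ll - cur_ll) / (abs(cur_ll) + 1e-10)
    beta <- cand
    cur_ll <- ll
    if (any(abs(beta) > 1e4)) break
    eta <- drop(X %*% beta)
    g_new <- drop(crossprod(X, y - stats::plogis(eta)))
    if (rel < tol && max(abs(g_new)) < 1e-6 &&
        max(abs(lambda * step)) < 1e-3) { converged <- TRUE; break }
  }
  se <- rep(NA_real_, p)
  vcov <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  if (converged) {
    eta <- drop(X %*% beta)
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    vc <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      dimnames(vc) <- list(colnames(X), colnames(X))
      vcov <- vc
      se <- sqrt(diag(vc))
    } else {
      converged <- FALSE
    }
  }
  k <- sum(y)
  n <- length(y)
  ll_null <- if (k %in% c(0, n)) 0 else k * log(k / n) + (n - k) * log(1 - k / n)
  new_fit("logistic",
          coefficients = stats::setNames(beta, colnames(X)),
          cutpoints = NULL,
          se = stats::setNames(se, colnames(X)), se_cutpoints = NULL,
          vcov = vcov, logLik = cur_ll, null_logLik = ll_null,
          converged = converged, iterations = iter, n = n,
          levels = c(0, 1), dropped = sc$dropped)
}

#' Pseudo-R-squared of a fitted model
#'
#' Nagelkerke's R^2 (default) is the Cox-Snell statistic
#' `1 - exp(2 (ll_null - ll_model) / n)` divided by its attainable maximum
#' `1 - exp(2 ll_null / n)`; McFadden's is `1 - ll_model / ll_null`.
#'
#' @param fit an `adjiv_fit`.
#' @param n number of observations; defaults to the fit's.
#' @param type one of `"nagelkerke"`, `"cox_snell"`, `"mcfadden"`.
#' @return a value in [0, 1].
#' @export
pseudo_r2 <- function(fit, n = fit$n, type = c("nagelkerke", "cox_snell", "mcfadden")) {
  type <- match.arg(type)
  if (is.null(fit$null_logLik) || is.na(fit$null_logLik))
    stop_usage("fit carries no null log-likelihood")
  cs <- 1 - exp(2 * (fit$null_logLik - fit$logLik) / n)
  switch(type,
         cox_snell = cs,
         nagelkerke = {
           mx <- 1 - exp(2 * fit$null_logLik / n)
           if (mx <= 0) 0 else cs / mx
         },
         mcfadden = 1 - fit$logLik / fit$null_logLik)
}

#' @rdname pseudo_r2
#' @export
nagelkerke_r2 <- function(fit, n = fit$n) pseudo_r2(fit, n, "nagelkerke")

#' @export
coef.adjiv_fit <- function(object, ...) object$coefficients

#' @export
vcov.adjiv_fit <- function(object, ...) object$vcov

#' @export
logLik.adjiv_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + length(object$cutpoints),
            nobs = object$n, class = "logLik")
}

#' @export
print.adjiv_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d, %s, %d iterations)\n",
              x$model, x$n,
              if (x$converged) "converged" else "NOT CONVERGED", x$iterations))
  if (length(x$cutpoints))
    cat("cut-points: ", paste(sprintf("%.4f", x$cutpoints), collapse = ", "), "\n")
  if (length(x$coefficients)) {
    tab <- cbind(beta = x$coefficients, se = x$se)
    print(round(tab, 4))
  }
  if (length(x$dropped))
    cat("dropped collinear columns: ", paste(x$dropped, collapse = ", "), "\n")
  cat(sprintf("logLik %.4f (null %.4f)\n", x$logLik, x$null_logLik))
  invisible(x)
}

#' Serialise a fit for structured logging
#'
#' @param fit an `adjiv_fit`.
#' @return a JSON string (coefficients, cut-points, SEs, log-likelihoods,
#'   convergence state; the covariance matrix is omitted).
#' @export
fit_json <- function(fit) {
  jsonlite::toJSON(fit[c("model", "coefficients", "cutpoints", "se",
                         "se_cutpoints", "logLik", "null_logLik",
                         "converged", "iterations", "n", "dropped")],
                   auto_unbox = TRUE, digits = NA, null = "null")
}
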