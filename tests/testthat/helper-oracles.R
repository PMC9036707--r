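# Independent oracles used to validate the package's own fitters and
# generators.  These deliberately avoid the package's Newton-Raphson code
# path: the likelihood is written out directly and maximised with optim()
# from several starts.

# Negative log-likelihood of the cumulative-logit model in an unconstrained
# parameterisation (first cut, log-increments, slopes).
oracle_po_negll <- function(par, x, y, K) {
  n_th <- K - 1L
  theta <- if (n_th == 1) par[1] else cumsum(c(par[1], exp(par[2:n_th])))
  beta <- par[n_th + seq_len(ncol(x))]
  eta <- if (ncol(x)) drop(x %*% beta) else numeric(nrow(x))
  up <- ifelse(y == K, Inf, theta[pmin(y, n_th)] + eta)
  lo <- ifelse(y == 1L, -Inf, theta[pmax(y - 1L, 1L)] + eta)
  p <- plogis(up) - plogis(lo)
  -sum(log(pmax(p, 1e-300)))
}

# Brute-force ML fit of the proportional-odds model: multi-start BFGS (and
# one Nelder-Mead polish) on the likelihood above.  Returns estimates in
# natural parameters.
oracle_po_fit <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  K <- length(unique(y))
  y <- match(y, sort(unique(y)))
  n_th <- K - 1L
  p <- ncol(x)
  cum <- pmin(pmax(cumsum(tabulate(y, K))[seq_len(n_th)] / length(y), 1e-4), 1 - 1e-4)
  th0 <- qlogis(cum)
  if (any(diff(th0) <= 0)) th0 <- qlogis(seq_len(n_th) / K)
  start0 <- c(th0[1], if (n_th > 1) log(pmax(diff(th0), 1e-3)), numeric(p))
  starts <- list(start0,
                 start0 + c(0.5, rep(0, n_th - 1), rep(0.3, p)),
                 start0 - c(0.5, rep(0, n_th - 1), rep(0.3, p)))
  best <- NULL
  for (s in starts) {
    o <- optim(s, oracle_po_negll, x = x, y = y, K = K, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, oracle_po_negll, x = x, y = y, K = K, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, oracle_po_negll, x = x, y = y, K = K, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta <- if (n_th == 1) best$par[1] else cumsum(c(best$par[1], exp(best$par[2:n_th])))
  list(cutpoints = theta, beta = best$par[n_th + seq_len(p)], logLik = -best$value)
}

# Central finite-difference Hessian of a scalar function.
numeric_hessian <- function(f, par, h = 1e-4) {
  k <- length(par)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(par + ei + ej) - f(par + ei - ej) - f(par - ei + ej) + f(par - ei - ej)) / (4 * h^2)
  }
  H
}

# Small, cheap study settings used by the Monte-Carlo property tests:
# hospitals keep the study's 150 patients each (the case-mix noise scale)
# but there are fewer of them.
scaled_hospitals <- function(n_hospitals = 20) {
  hospital_config(n_hospitals = n_hospitals, patients_per_hospital = 150)
}

scaled_config <- function(strategies = c("a", "b", "c", "d", "e", "f"),
                          n_reps = 200, seed = 4242, n_hospitals = 20) {
  study_config(hospitals = scaled_hospitals(n_hospitals),
               strategies = strategies, n_reps = n_reps, seed = seed)
}

# Run one (scenario, rho) cell of a config and summarise it; memoised so
# several test blocks can share the same simulations.
.mc_cache <- new.env(parent = emptyenv())
mc_cell <- function(config, scenario, rho = 0) {
  key <- paste(scenario, rho, config$seed, config$n_reps,
               config$hospitals$n_hospitals,
               paste(config$strategies, collapse = ""), sep = "|")
  if (!is.null(.mc_cache[[key]])) return(.mc_cache[[key]])
  est <- do.call(rbind, lapply(seq_len(config$n_reps), function(k) {
    run_replication(config, scenario, rho, k)
  }))
  out <- list(estimates = est, summary = summarize_estimates(est))
  .mc_cache[[key]] <- out
  out
}

cell_stat <- function(cell, strategy, what = "mean_beta") {
  s <- cell$summary
  s[[what]][s$strategy == strategy]
}
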