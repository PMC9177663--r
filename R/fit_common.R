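# Shared nonlinear least-squares machinery.
#
# All kinetic parameters are strictly positive, so every fit runs on the log
# scale (unconstrained Levenberg-Marquardt via minpack.lm::nls.lm) from
# several deterministic starts; the winner is the converged fit with the
# lowest cost, ties broken by the smallest log-parameter norm.

fit_multistart <- function(starts, residual_fn, n_obs,
                           maxiter = 200) {
  results <- list()
  for (s in starts) {
    lp0 <- log(s)
    if (any(!is.finite(lp0))) next
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = lp0,
        fn = function(lp) residual_fn(exp(lp)),
        control = minpack.lm::nls.lm.control(
          maxiter = maxiter, ftol = 1e-12, ptol = 1e-12, gtol = 0)),
      error = function(e) NULL)
    if (is.null(res) || !res$info %in% 1:4) next
    results[[length(results) + 1L]] <- res
  }
  if (!length(results)) {
    stop("nonlinear least squares failed to converge from any start")
  }
  dev <- vapply(results, stats::deviance, 0)
  lognorm <- vapply(results, function(r) sqrt(sum(r$par^2)), 0)
  best <- order(dev, lognorm)[1]
  fit <- results[[best]]

  theta <- exp(fit$par)
  npar <- length(theta)
  df <- n_obs - npar
  sigma2 <- if (df > 0) stats::deviance(fit) / df else NA_real_
  vcov_log <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  se_log <- sqrt(pmax(diag(vcov_log), 0))
  list(theta = theta,
       se = theta * se_log,          # delta method back to the natural scale
       se_log = se_log,
       vcov_log = vcov_log,
       rss = stats::deviance(fit), df = df,
       converged = TRUE, n_starts = length(starts),
       n_converged = length(results), info = fit$info)
}

# deterministic multiplicative jitter applied to a base start vector:
# the base itself plus 3 perturbed companions
jitter_starts <- function(base) {
  factors <- list(rep(1, length(base)),
                  rep(2, length(base)),
                  rep(0.5, length(base)),
                  rep_len(c(2, 0.5), length(base)))
  lapply(factors, function(f) base * f)
}

rel_err <- function(a, b) abs(a - b) / abs(b)
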