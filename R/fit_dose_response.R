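#' Fit a hyperbolic dose--response of velocity versus modifier
#'
#' Fits the mechanistic three-parameter hyperbola
#' \deqn{v(X) = \frac{v_0 + v_\infty X / X_{50}}{1 + X / X_{50}}}
#' to velocities measured over a modifier titration at fixed substrate
#' concentration. This is exactly the X-dependence of the general modifier
#' law (not an empirical Hill curve), so when the data come from that law
#' the fitted `X50` equals the analytic midpoint [half_effect()]. The
#' reported constant is an AC50 when the fitted asymptotes rise
#' (`vinf > v0`, activation) and an IC50 when they fall.
#'
#' The midpoint is profiled: for any candidate `X50` the asymptotes enter
#' linearly and are solved by ordinary least squares, leaving a 1-D
#' optimization in `log X50` — deterministic and free of starting-value
#' sensitivity.
#'
#' @param data data.frame with columns `X` (>= 5 distinct levels, the
#'   positive ones spanning >= 2 decades) and `v`.
#' @param S_fixed The fixed substrate concentration (annotation).
#' @param noise_floor Smallest asymptote separation regarded as a real
#'   effect; a fitted `|vinf - v0|` at or below it (or constant input) is
#'   an error: "no modification detected".
#' @return Object of class `dose_response_fit`: `coefficients`
#'   (`v0`, `vinf`, `X50`), `se`, `direction` ("activation" or
#'   "inhibition"), `label` ("AC50" or "IC50"), `S_fixed`, `rss`, `data`.
#' @export
fit_dose_response <- function(data, S_fixed = NA_real_, noise_floor = 0) {
  data <- as.data.frame(data)
  if (!all(c("X", "v") %in% names(data))) stop("'data' needs columns 'X' and 'v'")
  X <- data$X; v <- data$v
  if (length(unique(X)) < 5) stop("dose-response fit needs >= 5 modifier levels")
  pos <- X[X > 0]
  if (!length(pos) || max(pos) / min(pos) < 100) {
    stop("positive modifier levels must span >= 2 decades")
  }
  if (stats::sd(v) == 0) stop("no modification detected: velocities are constant")

  basis <- function(x50) {
    f <- X / (x50 + X)          # weight of vinf; (1 - f) weights v0
    cbind(1 - f, f)
  }
  rss_at <- function(lx) {
    B <- basis(exp(lx))
    fit <- stats::lm.fit(B, v)
    sum(fit$residuals^2)
  }
  lo <- log(min(pos)) - log(100)
  hi <- log(max(pos)) + log(100)
  # coarse grid then local refinement, so distant local minima are not missed
  lgrid <- seq(lo, hi, length.out = 200)
  r <- vapply(lgrid, rss_at, 0)
  l0 <- lgrid[which.min(r)]
  opt <- stats::optimize(rss_at, c(max(lo, l0 - 0.5), min(hi, l0 + 0.5)),
                         tol = 1e-12)
  X50 <- exp(opt$minimum)
  B <- basis(X50)
  ab <- stats::lm.fit(B, v)$coefficients
  v0 <- unname(ab[1]); vinf <- unname(ab[2])

  if (abs(vinf - v0) <= noise_floor) {
    stop("no modification detected: asymptote separation within the noise floor")
  }

  # standard errors from the local quadratic model at the optimum
  res <- v - B %*% ab
  n <- length(v); dfree <- n - 3
  se <- rep(NA_real_, 3)
  if (dfree > 0) {
    sigma2 <- sum(res^2) / dfree
    f <- X / (X50 + X)
    J <- cbind(1 - f, f, (vinf - v0) * X * X50 / (X50 + X)^2 * (-1 / X50))
    # d v / d X50 = -(vinf - v0) * X / (X50 + X)^2
    J[, 3] <- -(vinf - v0) * X / (X50 + X)^2
    se <- tryCatch(sqrt(diag(sigma2 * solve(crossprod(J)))),
                   error = function(e) rep(NA_real_, 3))
  }
  direction <- if (vinf > v0) "activation" else "inhibition"
  structure(
    list(coefficients = c(v0 = v0, vinf = vinf, X50 = X50),
         se = c(v0 = se[1], vinf = se[2], X50 = se[3]),
         direction = direction,
         label = if (direction == "activation") "AC50" else "IC50",
         S_fixed = S_fixed, rss = sum(res^2), n = n, data = data),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Hyperbolic dose-response (%s, n = %d%s)\n", x$direction, x$n,
              if (!is.na(x$S_fixed)) sprintf(", S = %g", x$S_fixed) else ""))
  cat(sprintf("  v0   = %.4g   vinf = %.4g (s^-1)\n", co["v0"], co["vinf"]))
  cat(sprintf("  %s = %.4g +/- %.3g\n", x$label, co["X50"], x$se["X50"]))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data$X else newdata$X
  co <- object$coefficients
  (co["v0"] + co["vinf"] * X / co["X50"]) / (1 + X / co["X50"])
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  d <- x$data
  pos <- d$X > 0
  xr <- range(d$X[pos])
  Xg <- exp(seq(log(xr[1] / 3), log(xr[2] * 3), length.out = 200))
  graphics::plot(d$X[pos], d$v[pos], log = "x", pch = 16,
                 xlab = "[X]", ylab = "v / Etot (1/s)", ...)
  graphics::lines(Xg, predict(x, data.frame(X = Xg)))
  graphics::abline(v = x$coefficients["X50"], lty = 2, col = "grey40")
  invisible(x)
}
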