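#' Global fit of the general (hyperbolic) modifier mechanism
#'
#' Estimates (kcat, Km, KX, alpha, beta) by weighted nonlinear least squares
#' of [modifier_velocity()] over the full (S, X) grid simultaneously — the
#' primary analysis; the per-level [fit_mm_family()] is the diagnostic
#' view. Starting values are derived from Michaelis--Menten fits at the
#' extreme modifier levels (kcat, Km from X = 0; alpha from the apparent-Km
#' ratio and beta from the apparent-kcat ratio at the largest X; KX from
#' the half-change point of the apparent Km), plus three deterministic
#' jittered companions. The attached [classify_mechanism()] call names the
#' mechanism of the fitted coefficients.
#'
#' Weighting: with `weights = "auto"` (default), inverse-variance weights
#' from per-(S, X) replicate standard deviations are used when every
#' condition has at least two replicates and positive spread; otherwise the
#' fit is unweighted.
#'
#' @param grid data.frame with columns `S`, `X`, `v` (normalized velocity)
#'   and optionally `replicate`; >= 4 distinct S levels and >= 3 distinct X
#'   levels including X = 0.
#' @param weights "auto" or "none".
#' @param epsilon Relative tolerance handed to [classify_mechanism()].
#' @return Object of class `modifier_fit`: `coefficients`
#'   (kcat, Km, KX, alpha, beta), `se`, `vcov_log`, `rss`, `df`,
#'   `mechanism`, `flags` ("poorly_determined" with the offending
#'   parameters when a relative standard error exceeds 100%, signalling
#'   structural non-identifiability such as no X coverage near KX),
#'   `convergence`, `data`, `units`.
#' @examples
#' truth <- kinetic_params(kcat = 24.35, Km = 18.79, KX = 50,
#'                         alpha = 30.39, beta = 0.09)
#' d <- expand.grid(S = c(0.5, 1, 2, 4, 8, 16), X = c(0, 20, 50, 100, 500))
#' d$v <- modifier_velocity(d$S, d$X, truth)
#' fit <- fit_modifier(d)
#' coef(fit)
#' fit$mechanism$label
#' @export
fit_modifier <- function(grid, weights = c("auto", "none"), epsilon = 0.05) {
  weights <- match.arg(weights)
  grid <- as.data.frame(grid)
  if (!all(c("S", "X", "v") %in% names(grid))) {
    stop("'grid' needs columns 'S', 'X' and 'v'")
  }
  S <- grid$S; X <- grid$X; v <- grid$v
  xs <- sort(unique(X))
  if (length(unique(S)) < 4) {
    stop("global modifier fit needs >= 4 distinct substrate levels")
  }
  if (length(xs) < 3 || min(xs) != 0) {
    stop("structural non-identifiability: need >= 3 modifier levels including X = 0")
  }

  w <- rep(1, length(v))
  if (weights == "auto") {
    key <- interaction(S, X, drop = TRUE)
    sds <- tapply(v, key, stats::sd)
    ns <- tapply(v, key, length)
    if (all(ns >= 2) && all(is.finite(sds)) && all(sds > 0)) {
      w <- 1 / (sds[key]^2)
      w <- as.numeric(w / mean(w))
    }
  }

  start <- modifier_seed(grid, xs)
  res <- fit_multistart(jitter_starts(start), function(th) {
    p <- list(kcat = th[1], Km = th[2], KX = th[3], alpha = th[4],
              beta = th[5], linear_case = FALSE)
    mdl <- p$kcat * (S / p$Km) * (1 + p$beta * X / (p$alpha * p$KX)) /
      (1 + S / p$Km + X / p$KX + S * X / (p$alpha * p$Km * p$KX))
    sqrt(w) * (v - mdl)
  }, n_obs = length(v))

  theta <- res$theta
  names(theta) <- names(res$se) <- c("kcat", "Km", "KX", "alpha", "beta")
  flags <- character(0)
  rel_se <- res$se_log   # SE of log(theta) ~ relative SE
  if (any(is.na(rel_se)) || any(rel_se > 1)) {
    bad <- names(theta)[is.na(rel_se) | rel_se > 1]
    flags <- c(flags, paste0("poorly_determined:", paste(bad, collapse = ",")))
  }

  mech <- classify_mechanism(theta[["alpha"]], theta[["beta"]],
                             epsilon = epsilon,
                             S_ref = stats::median(S), Km = theta[["Km"]])
  structure(
    list(coefficients = theta, se = res$se, vcov_log = res$vcov_log,
         rss = res$rss, df = res$df, n = length(v),
         mechanism = mech, flags = flags,
         weighted = !all(w == 1),
         convergence = res[c("n_starts", "n_converged", "info")],
         data = grid,
         units = list(conc_unit = attr(grid, "conc_unit") %||% "conc",
                      mod_unit = attr(grid, "mod_unit") %||% "mod",
                      Etot = attr(grid, "Etot") %||% NA_real_)),
    class = "modifier_fit"
  )
}

# seed construction from the per-level MM view
modifier_seed <- function(grid, xs) {
  f0 <- tryCatch(fit_mm(grid[grid$X == 0, c("S", "v")]), error = function(e) NULL)
  fmax <- tryCatch(fit_mm(grid[grid$X == max(xs), c("S", "v")]),
                   error = function(e) NULL)
  kcat0 <- if (!is.null(f0)) coef(f0)[["kcat"]] else 1.2 * max(grid$v)
  Km0 <- if (!is.null(f0)) coef(f0)[["Km"]] else stats::median(grid$S)
  alpha0 <- beta0 <- 1
  if (!is.null(f0) && !is.null(fmax)) {
    alpha0 <- max(coef(fmax)[["Km"]] / Km0, 1e-3)
    beta0 <- max(coef(fmax)[["kcat"]] / kcat0, 1e-3)
  }
  # KX seed: modifier level where the apparent Km has made half its total
  # move; fall back to the median positive level
  KX0 <- stats::median(xs[xs > 0])
  if (!is.null(f0) && !is.null(fmax) && length(xs) > 3) {
    mid <- (Km0 + coef(fmax)[["Km"]]) / 2
    kms <- vapply(xs[xs > 0], function(x) {
      f <- tryCatch(fit_mm(grid[grid$X == x, c("S", "v")]),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else coef(f)[["Km"]]
    }, 0)
    if (any(is.finite(kms))) {
      i <- which.min(abs(kms - mid))
      KX0 <- xs[xs > 0][i]
    }
  }
  c(kcat = unname(kcat0), Km = unname(Km0), KX = unname(KX0),
    alpha = unname(alpha0), beta = unname(beta0))
}

#' @export
print.modifier_fit <- function(x, ...) {
  cat("Global general-modifier fit (n =", x$n, "velocities",
      if (x$weighted) ", inverse-variance weighted" else "", ")\n", sep = "")
  co <- x$coefficients
  for (nm in names(co)) {
    cat(sprintf("  %-5s = %#.4g +/- %.3g\n", nm, co[nm], x$se[nm]))
  }
  cat("  mechanism:", x$mechanism$label, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.modifier_fit <- function(object, ...) object$coefficients

#' @export
summary.modifier_fit <- function(object, ...) {
  tab <- data.frame(Estimate = object$coefficients,
                    `Std. Error` = object$se,
                    check.names = FALSE)
  out <- list(table = tab, mechanism = object$mechanism,
              rss = object$rss, df = object$df, flags = object$flags,
              convergence = object$convergence)
  class(out) <- "summary.modifier_fit"
  out
}

#' @export
print.summary.modifier_fit <- function(x, ...) {
  cat("General (hyperbolic) modifier mechanism -- global fit\n\n")
  print(x$table, digits = 4)
  cat(sprintf("\nResidual sum of squares: %.4g on %d degrees of freedom\n",
              x$rss, x$df))
  cat("Mechanism:", x$mechanism$label, "\n")
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Kinetic parameter object from a fitted modifier model
#'
#' @param fit A `modifier_fit`.
#' @return A [kinetic_params()] object carrying the fitted coefficients.
#' @export
as_kinetic_params <- function(fit) {
  stopifnot(inherits(fit, "modifier_fit"))
  co <- fit$coefficients
  kinetic_params(co[["kcat"]], co[["Km"]], co[["KX"]], co[["alpha"]],
                 co[["beta"]],
                 Etot = fit$units$Etot,
                 conc_unit = fit$units$conc_unit,
                 mod_unit = fit$units$mod_unit)
}

#' @export
predict.modifier_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  co <- object$coefficients
  p <- kinetic_params(co[["kcat"]], co[["Km"]], co[["KX"]], co[["alpha"]],
                      co[["beta"]],
                      conc_unit = object$units$conc_unit,
                      mod_unit = object$units$mod_unit)
  as.numeric(modifier_velocity(d$S, d$X, p))
}

#' @export
residuals.modifier_fit <- function(object, ...) {
  object$data$v - predict(object)
}

#' @export
fitted.modifier_fit <- function(object, ...) predict(object)

#' Simulate velocity grids from a fitted modifier model
#'
#' Draws `nsim` noisy replicates of the fitted velocities at the observed
#' (S, X) design, with multiplicative Gaussian noise of coefficient of
#' variation `noise_cv` — a parametric bootstrap of the assay.
#'
#' @param object A `modifier_fit`.
#' @param nsim Number of simulated grids.
#' @param seed Optional integer seed.
#' @param noise_cv Noise CV; default 0.05.
#' @param ... Unused.
#' @return List of data.frames shaped like `object$data`.
#' @export
simulate.modifier_fit <- function(object, nsim = 1, seed = NULL,
                                  noise_cv = 0.05, ...) {
  withr_seed(seed)
  mu <- predict(object)
  lapply(seq_len(nsim), function(i) {
    d <- object$data
    d$v <- mu * (1 + truncnorm_pm4(length(mu), noise_cv))
    d
  })
}

#' Diagnostic plot of a modifier fit
#'
#' Michaelis--Menten view (points and fitted curves per modifier level) or
#' the Lineweaver--Burk double-reciprocal view.
#'
#' @param x A `modifier_fit`.
#' @param which `"mm"` or `"lineweaver"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.modifier_fit <- function(x, which = c("mm", "lineweaver"), ...) {
  which <- match.arg(which)
  d <- x$data
  xs <- sort(unique(d$X))
  cols <- grDevices::hcl.colors(max(length(xs), 2), "Zissou 1")
  p <- as_kinetic_params(x)
  if (which == "mm") {
    Sg <- seq(0, max(d$S) * 1.05, length.out = 200)
    vmax <- max(d$v, vapply(xs, function(xx) max(modifier_velocity(Sg, xx, p)), 0))
    graphics::plot(NA, xlim = c(0, max(d$S) * 1.05), ylim = c(0, vmax * 1.05),
                   xlab = sprintf("[S] (%s)", x$units$conc_unit),
                   ylab = "v / Etot (1/s)", ...)
    for (i in seq_along(xs)) {
      di <- d[d$X == xs[i], ]
      graphics::points(di$S, di$v, col = cols[i], pch = 16, cex = 0.7)
      graphics::lines(Sg, modifier_velocity(Sg, xs[i], p), col = cols[i])
    }
  } else {
    pos <- d$v > 0 & d$S > 0
    graphics::plot(1 / d$S[pos], 1 / d$v[pos],
                   col = cols[match(d$X[pos], xs)], pch = 16, cex = 0.7,
                   xlab = sprintf("1/[S] (1/%s)", x$units$conc_unit),
                   ylab = "Etot / v (s)", ...)
    for (i in seq_along(xs)) {
      ap <- apparent_parameters(xs[i], p)
      graphics::abline(a = 1 / ap$kcat_app, b = ap$Km_app / ap$kcat_app,
                       col = cols[i])
    }
  }
  graphics::legend("topright", legend = sprintf("X = %g", xs), col = cols,
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
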