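#' Fit the substrate-induced (SES) inhibition law
#'
#' Nonlinear least squares of [ses_velocity()] (single modifier level) or
#' [ses_modifier_velocity()] (several levels, adding the modifier coupling
#' constant `Kx`) to a velocity--substrate data set. `Ksi` is identifiable
#' only when the design extends beyond the velocity peak
#' `S* = sqrt(Km * Ksi)`; when the observed maximum sits at the largest
#' substrate level the fit is returned with the `ksi_unidentifiable` flag.
#'
#' @param data data.frame with columns `S`, `v`, optional `X` (absent or
#'   all-zero fits the plain SES law).
#' @return Object of class `ses_fit`: `coefficients` (`Vmax`, `Km`, `Ksi`
#'   and, with modifier levels, `Kx`), `se`, `flags`, `rss`, `df`, `data`.
#' @examples
#' q <- ses_params(Vmax = 0.5, Km = 300, Ksi = 400)
#' d <- data.frame(S = seq(100, 1000, by = 100))
#' d$v <- ses_velocity(d$S, q)
#' coef(fit_ses(d))
#' @export
fit_ses <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("S", "v") %in% names(data))) stop("'data' needs columns 'S' and 'v'")
  if (is.null(data$X)) data$X <- 0
  S <- data$S; v <- data$v; X <- data$X
  if (length(unique(S)) < 4) stop("SES fit needs >= 4 distinct S")
  with_modifier <- any(X > 0)

  # peak-interior check on the lowest modifier level (least inhibited)
  base <- data[data$X == min(X), ]
  mv <- tapply(base$v, base$S, mean)
  ss <- as.numeric(names(mv))
  flags <- character(0)
  if (ss[which.max(mv)] >= max(ss)) flags <- c(flags, "ksi_unidentifiable")

  S_peak <- ss[which.max(mv)]
  vmaxobs <- max(mv)
  half <- ss[mv >= vmaxobs / 2]
  Km0 <- if (length(half)) max(min(half) / 2, min(ss) / 4) else stats::median(ss) / 2
  Ksi0 <- if ("ksi_unidentifiable" %in% flags) 100 * max(ss)^2 / Km0
          else S_peak^2 / Km0
  Vmax0 <- vmaxobs * (1 + 2 * sqrt(Km0 / Ksi0))

  if (with_modifier) {
    Kx0 <- stats::median(X[X > 0])
    start <- c(Vmax = Vmax0, Km = Km0, Ksi = Ksi0, Kx = Kx0)
    resfn <- function(th) {
      v - th[1] * S / (th[2] + S + (S^2 / th[3]) * (1 + X / th[4]))
    }
  } else {
    start <- c(Vmax = Vmax0, Km = Km0, Ksi = Ksi0)
    resfn <- function(th) v - th[1] * S / (th[2] + S + S^2 / th[3])
  }
  res <- fit_multistart(jitter_starts(start), resfn, n_obs = length(v))
  theta <- res$theta; names(theta) <- names(res$se) <- names(start)
  if (res$se_log[match("Ksi", names(start))] > 1 &&
      !"ksi_unidentifiable" %in% flags) {
    flags <- c(flags, "ksi_unidentifiable")
  }
  structure(
    list(coefficients = theta, se = res$se, flags = flags,
         rss = res$rss, df = res$df, n = length(v),
         with_modifier = with_modifier, data = data),
    class = "ses_fit"
  )
}

#' @export
print.ses_fit <- function(x, ...) {
  cat("Substrate-induced (SES) inhibition fit\n")
  co <- x$coefficients
  for (nm in names(co)) {
    cat(sprintf("  %-4s = %#.4g +/- %.3g\n", nm, co[nm], x$se[nm]))
  }
  cat(sprintf("  velocity peak at S* = %.4g\n",
              sqrt(co[["Km"]] * co[["Ksi"]])))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ses_fit <- function(object, ...) object$coefficients

#' @export
predict.ses_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  if (is.null(d$X)) d$X <- 0
  co <- object$coefficients
  inh <- if ("Kx" %in% names(co)) (1 + d$X / co[["Kx"]]) else {
    if (any(d$X > 0)) stop("fit has no modifier coupling; newdata has X > 0")
    1
  }
  co[["Vmax"]] * d$S / (co[["Km"]] + d$S + (d$S^2 / co[["Ksi"]]) * inh)
}

#' @export
residuals.ses_fit <- function(object, ...) object$data$v - predict(object)

#' @export
plot.ses_fit <- function(x, ...) {
  d <- x$data
  xs <- sort(unique(d$X))
  cols <- grDevices::hcl.colors(max(length(xs), 2), "Zissou 1")
  Sg <- seq(min(d$S) / 4, max(d$S) * 1.05, length.out = 200)
  graphics::plot(NA, xlim = c(0, max(d$S) * 1.05), ylim = c(0, max(d$v) * 1.1),
                 xlab = "[S]", ylab = "v / Etot (1/s)", ...)
  for (i in seq_along(xs)) {
    di <- d[d$X == xs[i], ]
    graphics::points(di$S, di$v, col = cols[i], pch = 16, cex = 0.7)
    graphics::lines(Sg, predict(x, data.frame(S = Sg, X = xs[i])),
                    col = cols[i])
  }
  graphics::legend("topright", legend = sprintf("X = %g", xs), col = cols,
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
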