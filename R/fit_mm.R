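#' Fit the Michaelis--Menten law to velocities at one modifier level
#'
#' Nonlinear least squares of `v = kcat * S / (Km + S)` on normalized
#' velocities, started from the Lineweaver--Burk linearization seed plus
#' three deterministically jittered companions; the best converged start
#' wins.
#'
#' @param data data.frame with columns `S` (substrate concentration) and
#'   `v` (normalized velocity, s^-1); >= 4 distinct `S`, positive `v` for
#'   at least 3 of them.
#' @param X Modifier level annotation carried into the result (does not
#'   affect the fit).
#' @return Object of class `mm_fit`: `coefficients` (kcat, Km), `se`,
#'   `rss`, `df`, `n`, `X`, `flags` ("poorly_determined" when `Km` lands
#'   far outside the design range), `data`.
#' @examples
#' p <- kinetic_params(kcat = 1.74, Km = 1.60, KX = 50, alpha = 1, beta = 1)
#' d <- data.frame(S = c(0.5, 1, 2, 4, 8))
#' d$v <- mm_velocity(d$S, p)
#' coef(fit_mm(d))
#' @export
fit_mm <- function(data, X = NA_real_) {
  data <- as.data.frame(data)
  if (!all(c("S", "v") %in% names(data))) {
    stop("'data' needs columns 'S' and 'v'")
  }
  S <- data$S; v <- data$v
  if (length(unique(S)) < 4) stop("Michaelis-Menten fit needs >= 4 distinct S")
  if (sum(v > 0) < 3) stop("need positive velocities at >= 3 points")
  if (stats::sd(v) == 0) {
    stop("non-convergence: all velocities are equal (degenerate design)")
  }

  # Lineweaver-Burk seed from the positive velocities
  pos <- v > 0
  lb <- stats::lm(I(1 / v[pos]) ~ I(1 / S[pos]))
  kcat0 <- 1 / stats::coef(lb)[1]
  Km0 <- stats::coef(lb)[2] * kcat0
  if (!is.finite(kcat0) || kcat0 <= 0) kcat0 <- 1.2 * max(v)
  if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(S)

  starts <- jitter_starts(c(kcat = unname(kcat0), Km = unname(Km0)))
  res <- fit_multistart(starts, function(th) {
    v - th[1] * S / (th[2] + S)
  }, n_obs = length(v))

  flags <- character(0)
  if (res$theta[2] < min(S) / 1e3 || res$theta[2] > max(S) * 1e3) {
    flags <- c(flags, "poorly_determined")
  }
  structure(
    list(coefficients = c(kcat = unname(res$theta[1]),
                          Km = unname(res$theta[2])),
         se = c(kcat = unname(res$se[1]), Km = unname(res$se[2])),
         rss = res$rss, df = res$df, n = length(v), X = X,
         flags = flags, convergence = res[c("n_starts", "n_converged", "info")],
         data = data),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Michaelis-Menten fit (n = %d%s)\n", x$n,
              if (!is.na(x$X)) sprintf(", X = %g", x$X) else ""))
  cat(sprintf("  kcat = %.4g +/- %.3g s^-1\n", co["kcat"], x$se["kcat"]))
  cat(sprintf("  Km   = %.4g +/- %.3g\n", co["Km"], x$se["Km"]))
  cat(sprintf("  kcat/Km = %.4g\n", co["kcat"] / co["Km"]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) object$coefficients

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else newdata$S
  co <- object$coefficients
  co["kcat"] * S / (co["Km"] + S)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$v - predict(object)
}

#' Per-modifier-level Michaelis--Menten family fit
#'
#' Independent [fit_mm()] at every modifier level of a velocity grid — the
#' view that per-condition kinetic tables (kcat, Km, kcat/Km versus
#' modifier concentration) report. A failure at one level is recorded and
#' the remaining levels still return.
#'
#' @param grid data.frame with columns `S`, `X`, `v` (e.g. from
#'   [generate_velocity_grid()] or [extract_velocities()]).
#' @return Object of class `mm_family`: `fits` (named list of `mm_fit`,
#'   ordered by X), `errors` (named character), `X_levels`.
#' @export
fit_mm_family <- function(grid) {
  grid <- as.data.frame(grid)
  if (!all(c("S", "X", "v") %in% names(grid))) {
    stop("'grid' needs columns 'S', 'X' and 'v'")
  }
  xs <- sort(unique(grid$X))
  fits <- list(); errors <- character(0)
  for (x in xs) {
    key <- format(x, trim = TRUE)
    res <- tryCatch(fit_mm(grid[grid$X == x, c("S", "v")], X = x),
                    error = function(e) e)
    if (inherits(res, "error")) errors[key] <- conditionMessage(res)
    else fits[[key]] <- res
  }
  if (!length(fits)) stop("every modifier level failed to fit")
  structure(list(fits = fits, errors = errors, X_levels = xs),
            class = "mm_family")
}

#' @export
print.mm_family <- function(x, ...) {
  cat("Michaelis-Menten family over", length(x$X_levels), "modifier levels\n")
  print(efficiency_table(x), digits = 4)
  if (length(x$errors)) {
    cat("failed levels:\n")
    for (nm in names(x$errors)) cat(sprintf("  X = %s: %s\n", nm, x$errors[nm]))
  }
  invisible(x)
}

#' @export
coef.mm_family <- function(object, ...) {
  t(vapply(object$fits, coef, numeric(2)))
}
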