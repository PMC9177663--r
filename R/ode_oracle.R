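#' Steady-state velocity from the mass-action ODE system
#'
#' Brute-force realization of the four-state modifier scheme: integrates the
#' mass-action ODEs over enzyme species \{E, ES, EX, EXS\} at constant `S`
#' and `X` (substrate and modifier in excess) until all time derivatives fall
#' below `tol * Etot`, then returns `v = k3*[ES] + beta*k3*[EXS]`. Serves as
#' the independent oracle for [modifier_velocity()]: in the rapid-equilibrium
#' limit (binding rates much larger than `k3`; see [rates_for()]) the closed
#' form and the steady state agree.
#'
#' @param S,X Scalar substrate / modifier concentrations, >= 0, in the units
#'   implied by `r` (`k1` multiplies `S`, `k4` multiplies `X`).
#' @param r A [microscopic_rates()] object.
#' @param Etot Total enzyme concentration (any unit; the normalized velocity
#'   is independent of it).
#' @param tol Steady-state criterion: converged when `max |d/dt|` falls
#'   below `tol * Etot * k3` (the catalytic flux scale). Normalizing by `k3`
#'   keeps the criterion attainable in double precision when binding rates
#'   are scaled far above catalysis.
#' @param max_time Integration-time budget in multiples of the slowest
#'   relaxation scale; non-convergence within it is an error, never a
#'   silent value.
#' @param normalized If `TRUE` (default) return `v/Etot` in s^-1.
#' @return Steady-state velocity (scalar).
#' @export
ode_velocity <- function(S, X, r, Etot = 1, tol = 1e-9, max_time = 1e6,
                         normalized = TRUE) {
  stopifnot(inherits(r, "microscopic_rates"))
  stop_unless_scalar(S, X, Etot)
  if (S < 0 || X < 0) stop("'S' and 'X' must be >= 0")
  if (Etot <= 0) stop("'Etot' must be > 0")

  k1 <- r$k1; k2 <- r$k2; k3 <- r$k3; k4 <- r$k4; k5 <- r$k5
  a <- r$alpha; b <- r$beta

  deriv <- function(t, y, parms) {
    E <- y[1]; ES <- y[2]; EX <- y[3]; EXS <- y[4]
    dE   <- -k1 * S * E + (k2 + k3) * ES - k4 * X * E + k5 * EX
    dES  <- k1 * S * E - (k2 + k3) * ES - k4 * X * ES + a * k5 * EXS
    dEX  <- k4 * X * E - k5 * EX - k1 * S * EX + (a * k2 + b * k3) * EXS
    dEXS <- k4 * X * ES + k1 * S * EX - (a * k5 + a * k2 + b * k3) * EXS
    list(c(dE, dES, dEX, dEXS))
  }

  # relaxation is governed by the slowest first-order scale in the system
  slowest <- 1 / min(k2 + k3, k5, k1 * max(S, r$Km), k4 * max(X, r$KX))
  t_end <- 100 * slowest
  y <- c(E = Etot, ES = 0, EX = 0, EXS = 0)
  repeat {
    # an early return from the solver is harmless here: convergence is
    # established by the derivative criterion below, not by reaching t_end
    sol <- suppressWarnings(
      deSolve::ode(y, times = c(0, t_end), func = deriv, parms = NULL,
                   method = "lsoda", rtol = 1e-12, atol = 1e-14 * Etot,
                   maxsteps = 1e5))
    y <- sol[nrow(sol), -1]
    dmax <- max(abs(deriv(0, y, NULL)[[1]]))
    if (dmax < tol * Etot * k3) break
    t_end <- t_end * 4
    if (t_end > max_time * slowest) {
      stop(sprintf(
        "ODE oracle failed to reach steady state: max|d/dt| = %.3g after %g s",
        dmax, t_end / 4))
    }
  }
  v <- k3 * y[["ES"]] + b * k3 * y[["EXS"]]
  if (normalized) v / Etot else v
}
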