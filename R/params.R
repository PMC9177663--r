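#' Kinetic parameters of the general (hyperbolic) modifier mechanism
#'
#' Container for the parameter set of one enzyme--substrate--modifier triple
#' under the general (nonessential) modifier mechanism: the modifier X binds
#' free enzyme with dissociation constant `KX` and the ES complex with
#' `alpha * KX`, and the ternary EXS complex turns over at `beta * kcat`.
#'
#' `alpha` couples modifier binding to substrate binding (`alpha > 1` weakens
#' substrate binding in the presence of modifier, `alpha < 1` strengthens it);
#' `beta` scales catalysis from the ternary complex (`beta > 1` activation,
#' `beta < 1` partial inhibition, `beta = 0` complete inhibition).
#' `alpha = Inf` (or `KX = Inf`) is accepted as the no-ternary-complex limit,
#' in which the law degenerates to linear (non-hyperbolic) competitive-type
#' behaviour; such parameter sets carry `linear_case = TRUE`.
#'
#' All velocities computed from these parameters are normalized by total
#' enzyme (v/Etot, units s^-1); `Etot` is only needed to produce absolute
#' rates and may be `NA`.
#'
#' @param kcat Catalytic constant, s^-1. Positive.
#' @param Km Michaelis constant, in `conc_unit`. Positive.
#' @param KX Modifier dissociation constant from free enzyme, in `mod_unit`.
#'   Positive; `Inf` allowed (modifier never binds: silent modifier).
#' @param alpha Dimensionless coupling coefficient, > 0; `Inf` allowed.
#' @param beta Dimensionless catalytic coefficient, >= 0.
#' @param Etot Total enzyme concentration in `conc_unit` (optional).
#' @param conc_unit Unit tag for `Km`, `Etot` and all substrate
#'   concentrations ("mM" or "uM").
#' @param mod_unit Unit tag for `KX` and all modifier concentrations.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(kcat = 24.35, Km = 18.79, KX = 50, alpha = 30.39,
#'                     beta = 0.09, conc_unit = "mM", mod_unit = "uM")
#' mm_velocity(18.79, p)  # half-saturation: kcat / 2
#' @export
kinetic_params <- function(kcat, Km, KX, alpha, beta, Etot = NA_real_,
                           conc_unit = "mM", mod_unit = "uM") {
  stop_unless_scalar(kcat, Km, KX, alpha, beta)
  if (!is.finite(kcat) || kcat <= 0) stop("'kcat' must be finite and > 0")
  if (!is.finite(Km) || Km <= 0) stop("'Km' must be finite and > 0")
  if (is.na(KX) || KX <= 0) stop("'KX' must be > 0 (Inf allowed)")
  if (is.na(alpha) || alpha <= 0) {
    stop("'alpha' must be > 0: alpha = 0 leaves the modifier scheme undefined")
  }
  if (!is.finite(beta) || beta < 0) stop("'beta' must be finite and >= 0")
  if (!is.na(Etot) && Etot <= 0) stop("'Etot' must be > 0 when given")
  structure(
    list(kcat = kcat, Km = Km, KX = KX, alpha = alpha, beta = beta,
         Etot = Etot, conc_unit = conc_unit, mod_unit = mod_unit,
         linear_case = is.infinite(alpha) || is.infinite(KX)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("General modifier mechanism parameters\n")
  cat(sprintf("  kcat  = %g s^-1\n", x$kcat))
  cat(sprintf("  Km    = %g %s\n", x$Km, x$conc_unit))
  cat(sprintf("  KX    = %g %s\n", x$KX, x$mod_unit))
  cat(sprintf("  alpha = %g   beta = %g\n", x$alpha, x$beta))
  if (!is.na(x$Etot)) cat(sprintf("  Etot  = %g %s\n", x$Etot, x$conc_unit))
  if (x$linear_case) cat("  [no-ternary-complex (linear) limit]\n")
  invisible(x)
}

#' Parameters of the substrate-induced (SES) inhibition law
#'
#' Substrate-induced inhibition arises when a second substrate molecule binds
#' the ES complex, forming a dead-end substrate--enzyme--substrate (SES)
#' ternary complex with dissociation constant `Ksi`. `Ksi = Inf` recovers
#' plain Michaelis--Menten behaviour. An optional modifier constant `Kx`
#' couples a modifier to the SES branch: the inhibition term is multiplied by
#' `(1 + X / Kx)`, so the modifier accentuates substrate inhibition
#' dose-dependently.
#'
#' @param Vmax Maximal velocity over Etot, s^-1. Positive.
#' @param Km Michaelis constant, in `conc_unit`.
#' @param Ksi Substrate-inhibition dissociation constant, same unit as `Km`;
#'   `Inf` allowed.
#' @param Kx Modifier coupling constant in `mod_unit`; `NA` (default) means
#'   no modifier effect is modelled.
#' @param conc_unit,mod_unit Unit tags.
#' @return An object of class `ses_params`.
#' @export
ses_params <- function(Vmax, Km, Ksi, Kx = NA_real_,
                       conc_unit = "uM", mod_unit = "uM") {
  stop_unless_scalar(Vmax, Km, Ksi)
  if (!is.finite(Vmax) || Vmax <= 0) stop("'Vmax' must be finite and > 0")
  if (!is.finite(Km) || Km <= 0) stop("'Km' must be finite and > 0")
  if (is.na(Ksi) || Ksi <= 0) stop("'Ksi' must be > 0 (Inf allowed)")
  if (!is.na(Kx) && Kx <= 0) stop("'Kx' must be > 0 when given")
  structure(
    list(Vmax = Vmax, Km = Km, Ksi = Ksi, Kx = Kx,
         conc_unit = conc_unit, mod_unit = mod_unit),
    class = "ses_params"
  )
}

#' @export
print.ses_params <- function(x, ...) {
  cat("Substrate-induced (SES) inhibition parameters\n")
  cat(sprintf("  Vmax/Etot = %g s^-1\n", x$Vmax))
  cat(sprintf("  Km  = %g %s   Ksi = %g %s\n",
              x$Km, x$conc_unit, x$Ksi, x$conc_unit))
  if (!is.na(x$Kx)) cat(sprintf("  Kx  = %g %s (modifier-coupled)\n",
                                x$Kx, x$mod_unit))
  invisible(x)
}

#' Mass-action rate constants of the four-state modifier scheme
#'
#' The microscopic realization of the general modifier mechanism over states
#' E, ES, EX, EXS: `E + S <-> ES` (k1, k2), `ES -> E + P` (k3),
#' `E + X <-> EX` (k4, k5), `ES + X <-> EXS` (association k4, dissociation
#' `alpha * k5`), `EX + S <-> EXS` (association k1, dissociation
#' `alpha * k2`), `EXS -> EX + P` (`beta * k3`). The same `alpha` couples
#' both entries into EXS, so the thermodynamic box around E/ES/EXS/EX closes:
#' the product of equilibrium constants around the cycle is 1.
#'
#' Derived constants: `KS = k2/k1`, `KX = k5/k4`, `Km = (k2 + k3)/k1`,
#' `kcat = k3`.
#'
#' @param k1 E+S association, per conc-unit per s.
#' @param k2 ES dissociation, s^-1.
#' @param k3 catalytic step, s^-1.
#' @param k4 E+X association, per mod-unit per s.
#' @param k5 EX dissociation, s^-1.
#' @param alpha,beta Coupling coefficients as in [kinetic_params()].
#' @return Object of class `microscopic_rates` with elements k1..k5, alpha,
#'   beta and derived KS, KX, Km, kcat.
#' @seealso [rates_for()] to build rates consistent with a
#'   [kinetic_params()] set, [ode_velocity()] for the ODE oracle.
#' @export
microscopic_rates <- function(k1, k2, k3, k4, k5, alpha, beta) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all rate constants k1..k5 must be finite and > 0")
  }
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be finite and > 0")
  if (!is.finite(beta) || beta < 0) stop("'beta' must be finite and >= 0")
  structure(
    list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
         alpha = alpha, beta = beta,
         KS = k2 / k1, KX = k5 / k4, Km = (k2 + k3) / k1, kcat = k3),
    class = "microscopic_rates"
  )
}

#' Microscopic rates consistent with a macroscopic parameter set
#'
#' Builds mass-action rates whose derived Km, kcat, KX, alpha, beta equal
#' those of `p` exactly, with binding steps faster than catalysis by the
#' factor `scale` (the rapid-equilibrium limit is approached as
#' `scale -> Inf`). Specifically `k3 = kcat`, `k1 = scale * k3 / Km`,
#' `k2 = k1 * Km - k3`, `k4 = scale * k3 / KX`, `k5 = KX * k4`.
#'
#' @param p A [kinetic_params()] object with finite `alpha` and `KX`.
#' @param scale Ratio of binding rates to `k3`; must exceed 1.
#' @return A [microscopic_rates()] object.
#' @export
rates_for <- function(p, scale = 1e4) {
  stopifnot(inherits(p, "kinetic_params"))
  if (p$linear_case) {
    stop("microscopic rates require finite 'alpha' and 'KX'")
  }
  if (scale <= 1) stop("'scale' must exceed 1 so that k2 = k1*Km - k3 > 0")
  k3 <- p$kcat
  k1 <- scale * k3 / p$Km
  k2 <- k1 * p$Km - k3
  k4 <- scale * k3 / p$KX
  k5 <- p$KX * k4
  microscopic_rates(k1, k2, k3, k4, k5, p$alpha, p$beta)
}

# internal: all args length-1 numeric
stop_unless_scalar <- function(...) {
  args <- list(...)
  nm <- vapply(substitute(list(...))[-1], deparse, "")
  for (i in seq_along(args)) {
    if (!is.numeric(args[[i]]) || length(args[[i]]) != 1L) {
      stop(sprintf("'%s' must be a single numeric value", nm[i]))
    }
  }
  invisible(TRUE)
}

# internal: reject concentration vectors tagged with a different unit than
# the parameter set expects; untagged inputs are assumed consistent
check_unit <- function(x, expected, what) {
  u <- attr(x, "unit")
  if (!is.null(u) && !identical(u, expected)) {
    stop(sprintf("unit mismatch: '%s' is tagged '%s' but parameters use '%s'",
                 what, u, expected))
  }
  invisible(TRUE)
}
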