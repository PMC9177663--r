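#' Michaelis--Menten velocity
#'
#' Normalized initial velocity `v/Etot = kcat * S / (Km + S)`.
#'
#' @param S Substrate concentration(s), same unit as `p$Km`, >= 0.
#' @param p A [kinetic_params()] object.
#' @return Normalized velocity in s^-1, same length as `S`.
#' @export
mm_velocity <- function(S, p) {
  stopifnot(inherits(p, "kinetic_params"))
  check_unit(S, p$conc_unit, "S")
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("substrate concentration 'S' must be finite and >= 0")
  }
  p$kcat * S / (p$Km + S)
}

#' General (hyperbolic) modifier velocity
#'
#' Normalized velocity of the general nonessential modifier mechanism,
#' \deqn{v/E_t = \frac{k_{cat}\,(S/K_m)\,(1 + \beta X/(\alpha K_X))}
#'  {1 + S/K_m + X/K_X + S X/(\alpha K_m K_X)}.}
#' At `X = 0` this reduces to [mm_velocity()]; as `X -> Inf` it tends to
#' `beta * kcat * S / (alpha * Km + S)`. At fixed `S` the velocity is a
#' monotone hyperbola in `X`; the direction of modification (activation vs
#' inhibition) is the sign of `beta * (Km + S) - (alpha * Km + S)`.
#'
#' In the no-ternary-complex limit (`alpha` or `KX` infinite) the EXS terms
#' vanish and the result carries attribute `linear_case = TRUE`.
#'
#' @param S Substrate concentration(s), unit of `p$Km`, >= 0.
#' @param X Modifier concentration(s), unit of `p$KX`, >= 0. Recycled
#'   against `S`.
#' @param p A [kinetic_params()] object.
#' @return Normalized velocity in s^-1.
#' @export
modifier_velocity <- function(S, X, p) {
  stopifnot(inherits(p, "kinetic_params"))
  check_unit(S, p$conc_unit, "S")
  check_unit(X, p$mod_unit, "X")
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("substrate concentration 'S' must be finite and >= 0")
  }
  if (any(is.na(X)) || any(X < 0)) {
    stop("modifier concentration 'X' must be >= 0")
  }
  # 1/(alpha*KX) -> 0 in the linear (no ternary complex) limit
  inv_aKX <- if (p$linear_case) 0 else 1 / (p$alpha * p$KX)
  xKX <- if (is.infinite(p$KX)) 0 * X else X / p$KX
  num <- p$kcat * (S / p$Km) * (1 + p$beta * X * inv_aKX)
  den <- 1 + S / p$Km + xKX + S * X * inv_aKX / p$Km
  v <- num / den
  if (p$linear_case) attr(v, "linear_case") <- TRUE
  v
}

#' Apparent Michaelis--Menten parameters at a fixed modifier concentration
#'
#' At any fixed `X` the general modifier law is exactly Michaelis--Menten in
#' `S` with
#' `kcat_app = kcat * (1 + beta*X/(alpha*KX)) / (1 + X/(alpha*KX))` and
#' `Km_app = Km * (1 + X/KX) / (1 + X/(alpha*KX))`. This is the view a
#' per-modifier-level Michaelis--Menten table reports.
#'
#' @param X Modifier concentration(s), unit of `p$KX`, >= 0.
#' @param p A [kinetic_params()] object.
#' @return A data.frame with columns `X`, `kcat_app`, `Km_app`,
#'   `efficiency_app` (= kcat_app / Km_app).
#' @export
apparent_parameters <- function(X, p) {
  stopifnot(inherits(p, "kinetic_params"))
  check_unit(X, p$mod_unit, "X")
  if (any(is.na(X)) || any(X < 0)) {
    stop("modifier concentration 'X' must be >= 0")
  }
  inv_aKX <- if (p$linear_case) 0 else 1 / (p$alpha * p$KX)
  xKX <- if (is.infinite(p$KX)) 0 * X else X / p$KX
  kcat_app <- p$kcat * (1 + p$beta * X * inv_aKX) / (1 + X * inv_aKX)
  Km_app <- p$Km * (1 + xKX) / (1 + X * inv_aKX)
  data.frame(X = X, kcat_app = kcat_app, Km_app = Km_app,
             efficiency_app = kcat_app / Km_app)
}

#' Exact half-effect modifier concentration (analytic AC50/IC50)
#'
#' The modifier concentration at which the velocity lies exactly midway
#' between `v(X = 0)` and `v(X -> Inf)` at fixed substrate concentration.
#' For the hyperbolic modifier law this midpoint is analytic:
#' \deqn{X_{50} = \alpha K_X \frac{K_m + S}{\alpha K_m + S}.}
#' It is an AC50 when the modifier activates at this `S` and an IC50 when it
#' inhibits. For `alpha = 1`, `X50 = KX` at every `S`; likewise at `S = 0`.
#'
#' @param S Substrate concentration(s), unit of `p$Km`, >= 0.
#' @param p A [kinetic_params()] object; must actually modify the velocity
#'   (`alpha != 1` or `beta != 1`), otherwise the midpoint is undefined.
#' @return X50 in the modifier unit of `p`.
#' @export
half_effect <- function(S, p) {
  stopifnot(inherits(p, "kinetic_params"))
  check_unit(S, p$conc_unit, "S")
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("substrate concentration 'S' must be finite and >= 0")
  }
  if (p$alpha == 1 && p$beta == 1) {
    stop("undefined midpoint: alpha = beta = 1 produces no modification")
  }
  if (p$linear_case) {
    stop("undefined midpoint: no-ternary-complex limit has no finite v(Inf)")
  }
  # per-S flatness: v(0) == v(Inf) when beta*(Km+S) == alpha*Km + S
  flat <- abs(p$beta * (p$Km + S) - (p$alpha * p$Km + S)) <
    1e-12 * (p$alpha * p$Km + S)
  if (any(flat)) {
    stop("undefined midpoint: v(0) = v(Inf) at the requested S")
  }
  p$alpha * p$KX * (p$Km + S) / (p$alpha * p$Km + S)
}

#' Substrate-induced (SES) inhibition velocity
#'
#' `v/Etot = Vmax * S / (Km + S + S^2/Ksi)`: unimodal in `S`, maximal at
#' `S* = sqrt(Km * Ksi)` and strictly decreasing beyond it, as expected when
#' a second substrate molecule forms a dead-end SES complex.
#'
#' @param S Substrate concentration(s), unit of `q$Km`, >= 0.
#' @param q A [ses_params()] object.
#' @return Normalized velocity in s^-1.
#' @export
ses_velocity <- function(S, q) {
  stopifnot(inherits(q, "ses_params"))
  check_unit(S, q$conc_unit, "S")
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("substrate concentration 'S' must be finite and >= 0")
  }
  sq <- if (is.infinite(q$Ksi)) 0 * S else S^2 / q$Ksi
  q$Vmax * S / (q$Km + S + sq)
}

#' SES velocity with a modifier accentuating substrate inhibition
#'
#' One-parameter modifier coupling to the SES branch:
#' `v/Etot = Vmax * S / (Km + S + (S^2/Ksi) * (1 + X/Kx))`. At `X = 0` this
#' equals [ses_velocity()]; in the substrate-inhibited regime the velocity
#' decreases strictly with `X` (dose-dependent accentuation); as `X -> Inf`
#' the velocity tends to 0 for any `S > 0`.
#'
#' @param S Substrate concentration(s), unit of `q$Km`, >= 0.
#' @param X Modifier concentration(s), unit of `q$Kx`, >= 0.
#' @param q A [ses_params()] object with `Kx` set.
#' @return Normalized velocity in s^-1.
#' @export
ses_modifier_velocity <- function(S, X, q) {
  stopifnot(inherits(q, "ses_params"))
  if (is.na(q$Kx)) {
    stop("'q$Kx' is not set: modifier coupling constant required")
  }
  check_unit(S, q$conc_unit, "S")
  check_unit(X, q$mod_unit, "X")
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("substrate concentration 'S' must be finite and >= 0")
  }
  if (any(is.na(X)) || any(X < 0)) {
    stop("modifier concentration 'X' must be >= 0")
  }
  sq <- if (is.infinite(q$Ksi)) 0 * S else S^2 / q$Ksi
  q$Vmax * S / (q$Km + S + sq * (1 + X / q$Kx))
}
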