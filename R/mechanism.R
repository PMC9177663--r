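#' Classify a fitted (alpha, beta) pair into the hyperbolic modifier taxonomy
#'
#' Names the mechanism of a nonessential (hyperbolic) modifier from its two
#' coupling coefficients. The *specific* component acts through binding
#' (`alpha > 1` inhibitory, `alpha < 1` activating); the *catalytic*
#' component acts through turnover of the ternary complex (`beta < 1`
#' inhibitory, `beta > 1` activating). When both components are present the
#' dominant one is the coefficient farther from neutrality on the log scale
#' (`|ln alpha|` vs `|ln beta|`), giving labels such as
#' "hyperbolic predominantly specific inhibition".
#'
#' Decision order (all comparisons relative, tolerance `epsilon`):
#' 1. `alpha ~ beta`: purely catalytic modification — the apparent
#'    efficiency kcat/Km is unchanged by the modifier ("hyperbolic catalytic
#'    activation" if `beta > 1`, "... inhibition" if `beta < 1`,
#'    "no modification" if also `beta ~ 1`). Checked first so that a
#'    constrained-looking `alpha = beta` fit maps to the catalytic-only
#'    label.
#' 2. `alpha ~ 1`, `beta` not: hyperbolic catalytic (in)activation.
#' 3. `beta ~ 1`, `alpha` not: hyperbolic specific inhibition
#'    (`alpha > 1`) or activation (`alpha < 1`).
#' 4. Otherwise mixed. If the two components agree in direction the label
#'    direction follows them; if they conflict, the net direction at a
#'    reference substrate concentration is the sign of
#'    `beta*(Km + S) - (alpha*Km + S)` and `S_ref` and `Km` are required.
#'
#' `beta = 0` lies outside the hyperbolic family (complete, linear-type
#' catalytic inhibition) and is labelled as such with a warning flag.
#'
#' @param alpha,beta Coupling coefficients; `alpha > 0`, `beta >= 0`.
#' @param epsilon Relative tolerance for the approximate-equality decisions,
#'   in (0, 0.5). Default 0.05.
#' @param S_ref,Km Reference substrate concentration and Michaelis constant
#'   (same unit); required only in the discordant mixed branch.
#' @return An object of class `mechanism_call` with fields
#'   `specific_component`, `catalytic_component` (each "inhibitory",
#'   "activating" or "absent"), `dominance` ("specific", "catalytic",
#'   "balanced" or "none"), `label`, `linear_flag`, `epsilon`.
#' @examples
#' classify_mechanism(30.39, 0.09)$label
#' classify_mechanism(0.82, 25.4)$label
#' classify_mechanism(7.88, 7.88)$label
#' @export
classify_mechanism <- function(alpha, beta, epsilon = 0.05,
                               S_ref = NULL, Km = NULL) {
  stop_unless_scalar(alpha, beta, epsilon)
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be finite and > 0")
  if (!is.finite(beta) || beta < 0) stop("'beta' must be finite and >= 0")
  if (epsilon <= 0 || epsilon >= 0.5) stop("'epsilon' must be in (0, 0.5)")

  releq <- function(a, b) abs(a - b) / max(a, b) <= epsilon

  spec_comp <- if (releq(alpha, 1)) "absent"
               else if (alpha > 1) "inhibitory" else "activating"

  if (beta == 0) {
    out <- mechanism_call(spec_comp, "inhibitory", "catalytic",
                          "complete (linear) catalytic inhibition",
                          epsilon, linear_flag = TRUE)
    warning("beta = 0: complete (linear) inhibition, outside the hyperbolic family")
    return(out)
  }

  cat_comp <- if (releq(beta, 1)) "absent"
              else if (beta > 1) "activating" else "inhibitory"

  # 1. alpha ~ beta: efficiency-preserving, purely catalytic modification
  if (releq(alpha, beta)) {
    if (releq(beta, 1)) {
      return(mechanism_call("absent", "absent", "none", "no modification",
                            epsilon))
    }
    dir <- if (beta > 1) "activation" else "inhibition"
    return(mechanism_call("absent",
                          if (beta > 1) "activating" else "inhibitory",
                          "catalytic",
                          paste("hyperbolic catalytic", dir), epsilon))
  }

  # 2/3. one coefficient neutral
  if (spec_comp == "absent" && cat_comp == "absent") {
    return(mechanism_call("absent", "absent", "none", "no modification",
                          epsilon))
  }
  if (spec_comp == "absent") {
    dir <- if (cat_comp == "activating") "activation" else "inhibition"
    return(mechanism_call("absent", cat_comp, "catalytic",
                          paste("hyperbolic catalytic", dir), epsilon))
  }
  if (cat_comp == "absent") {
    dir <- if (spec_comp == "activating") "activation" else "inhibition"
    return(mechanism_call(spec_comp, "absent", "specific",
                          paste("hyperbolic specific", dir), epsilon))
  }

  # 4. mixed
  dom <- dominance_of(alpha, beta, epsilon)
  same_dir <- (spec_comp == "inhibitory" && cat_comp == "inhibitory") ||
    (spec_comp == "activating" && cat_comp == "activating")
  if (same_dir) {
    dir <- if (spec_comp == "inhibitory") "inhibition" else "activation"
  } else {
    if (is.null(S_ref) || is.null(Km)) {
      stop("discordant specific/catalytic components: supply 'S_ref' and 'Km' ",
           "so the net direction sign beta*(Km+S) - (alpha*Km+S) can be evaluated")
    }
    net <- beta * (Km + S_ref) - (alpha * Km + S_ref)
    dir <- if (net > 0) "activation" else "inhibition"
  }
  label <- switch(dom,
    specific  = paste("hyperbolic predominantly specific", dir),
    catalytic = paste("hyperbolic predominantly catalytic", dir),
    balanced  = paste("hyperbolic mixed (balanced)", dir)
  )
  mechanism_call(spec_comp, cat_comp, dom, label, epsilon)
}

# internal: which component sits farther from neutrality on the log scale
dominance_of <- function(alpha, beta, epsilon) {
  da <- abs(log(alpha)); db <- abs(log(beta))
  if (abs(da - db) <= epsilon * max(da, db)) "balanced"
  else if (da > db) "specific" else "catalytic"
}

mechanism_call <- function(spec, cat, dom, label, epsilon,
                           linear_flag = FALSE) {
  structure(
    list(specific_component = spec, catalytic_component = cat,
         dominance = dom, label = label, epsilon = epsilon,
         linear_flag = linear_flag),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Mechanism:", x$label, "\n")
  cat(sprintf("  specific component:  %s\n", x$specific_component))
  cat(sprintf("  catalytic component: %s\n", x$catalytic_component))
  cat(sprintf("  dominance: %s   (epsilon = %g)\n", x$dominance, x$epsilon))
  if (x$linear_flag) cat("  [outside the hyperbolic family]\n")
  invisible(x)
}

#' @export
format.mechanism_call <- function(x, ...) x$label
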