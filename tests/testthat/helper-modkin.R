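# Shared fixtures: reference parameter sets and in-code data builders.

# Reference coupling/turnover constants for LTA4H aminopeptidase hydrolysis
# of the three pNA substrates modulated by 4MDM (KX is a simulation choice).
arg_params <- function(KX = 50) {
  kinetic_params(kcat = 24.35, Km = 18.79, KX = KX, alpha = 30.39,
                 beta = 0.09, conc_unit = "mM", mod_unit = "uM")
}
ala_params <- function(KX = 50) {
  kinetic_params(kcat = 1.74, Km = 1.60, KX = KX, alpha = 0.82,
                 beta = 25.4, conc_unit = "mM", mod_unit = "uM")
}
pro_params <- function(KX = 50) {
  kinetic_params(kcat = 0.19, Km = 0.84, KX = KX, alpha = 7.88,
                 beta = 7.88, conc_unit = "mM", mod_unit = "uM")
}

# noise-free velocity grid straight from the law (no design object needed)
law_grid <- function(p, S = c(0.5, 1, 2, 4, 8), X = c(0, 10, 20, 40, 80)) {
  d <- expand.grid(S = S, X = X)
  d$v <- as.numeric(modifier_velocity(d$S, d$X, p))
  d
}

# random admissible parameter draws for property-style loops
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_params(kcat = exp(stats::runif(1, -1, 3)),
                   Km = exp(stats::runif(1, -1, 3)),
                   KX = exp(stats::runif(1, 0, 5)),
                   alpha = exp(stats::runif(1, -2.5, 2.5)),
                   beta = exp(stats::runif(1, -2.5, 2.5)))
  })
}

# noise-free calibration line: A405 = 0.05 + 0.9 * [P]
flat_curve <- function() {
  conc <- seq(0, 1, length.out = 6)
  fit_standard_curve(conc, 0.05 + 0.9 * conc)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
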