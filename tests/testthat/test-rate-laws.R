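test_that("Michaelis-Menten law obeys its defining identities", {
  p <- arg_params()
  expect_equal(mm_velocity(0, p), 0)
  expect_equal(mm_velocity(p$Km, p), p$kcat / 2)
  # half-saturation from the Arg-pNA zero-modifier constants
  expect_equal(mm_velocity(18.79, p), 12.175)
  # monotone nondecreasing, saturating at kcat
  S <- seq(0, 500, length.out = 200)
  v <- mm_velocity(S, p)
  expect_true(all(diff(v) >= 0))
  expect_lt(abs(mm_velocity(1e9, p) - p$kcat) / p$kcat, 1e-6)
})

test_that("rate laws reject bad inputs with informative messages", {
  p <- arg_params()
  expect_error(mm_velocity(-1, p), "'S'")
  Sbad <- structure(2, unit = "uM")
  expect_error(mm_velocity(Sbad, p), "unit mismatch.*'S'")
  expect_error(modifier_velocity(2, -5, p), "'X'")
  expect_error(kinetic_params(kcat = 1, Km = 1, KX = 1, alpha = 0, beta = 1),
               "alpha")
  expect_error(kinetic_params(kcat = -1, Km = 1, KX = 1, alpha = 1, beta = 1),
               "kcat")
})

test_that("modifier law reduces to Michaelis-Menten at X = 0", {
  for (p in random_params(20)) {
    S <- c(0, 0.3, 1, 5, 50)
    expect_equal(as.numeric(modifier_velocity(S, 0, p)), mm_velocity(S, p))
  }
})

test_that("modifier law saturates to the beta/alpha-modified branch", {
  for (p in random_params(10, seed = 7)) {
    S <- c(0.5, 2, 20)
    vinf <- p$beta * p$kcat * S / (p$alpha * p$Km + S)
    v <- as.numeric(modifier_velocity(S, 1e6 * p$KX, p))
    expect_rel_equal(v, vinf, 1e-3)
  }
})

test_that("v(X) at fixed S is a monotone hyperbola (no interior extremum)", {
  for (p in random_params(15, seed = 11)) {
    X <- 10^seq(-3, 3, length.out = 60) * p$KX
    v <- as.numeric(modifier_velocity(1.7, X, p))
    d <- diff(v)
    d <- d[abs(d) > 1e-13 * max(abs(v))]
    if (length(d)) expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("apparent parameters reproduce the law and its invariances", {
  p <- arg_params()
  a0 <- apparent_parameters(0, p)
  expect_equal(a0$kcat_app, p$kcat)
  expect_equal(a0$Km_app, p$Km)

  # at any X the law is exactly MM in S with the apparent parameters
  for (X in c(0.5, 20, 300)) {
    ap <- apparent_parameters(X, p)
    S <- c(0.2, 1, 5, 40)
    expect_equal(as.numeric(modifier_velocity(S, X, p)),
                 ap$kcat_app * S / (ap$Km_app + S))
  }

  # alpha = 1: Km unchanged at every X
  p1 <- kinetic_params(kcat = 2, Km = 1.3, KX = 10, alpha = 1, beta = 4)
  expect_equal(apparent_parameters(c(0, 1, 10, 100), p1)$Km_app,
               rep(1.3, 4))

  # alpha = beta: catalytic efficiency independent of X
  pp <- pro_params()
  eff <- apparent_parameters(c(0.1, 1, 10) * pp$KX, pp)$efficiency_app
  expect_rel_equal(eff, rep(pp$kcat / pp$Km, 3), 1e-9)
})

test_that("apparent efficiency at alpha = beta is X-independent in the S->0 limit", {
  pp <- pro_params()
  S <- 1e-9
  eff0 <- as.numeric(modifier_velocity(S, 0, pp)) / S
  eff1 <- as.numeric(modifier_velocity(S, 10 * pp$KX, pp)) / S
  expect_lt(abs(eff1 - eff0) / eff0, 1e-9)
})

test_that("half-effect concentration is the exact hyperbola midpoint", {
  # closed form: alpha = 1 collapses to KX at any S; so does S = 0
  p1 <- kinetic_params(kcat = 2, Km = 1.3, KX = 10, alpha = 1, beta = 4)
  expect_equal(half_effect(c(0, 1, 7), p1), rep(10, 3))
  p2 <- arg_params()
  expect_equal(half_effect(0, p2), p2$KX)

  # worked example: Km = 1.60 mM, alpha = 0.82, KX = 5 uM, S = 1 mM
  p3 <- kinetic_params(kcat = 1.74, Km = 1.60, KX = 5.0, alpha = 0.82,
                       beta = 25.4)
  expect_equal(half_effect(1.0, p3), 0.82 * 5.0 * 2.60 / 2.312,
               tolerance = 1e-12)

  # midpoint identity and bisection cross-check on random draws
  for (p in random_params(15, seed = 3)) {
    if (abs(p$alpha - 1) < 1e-6 && abs(p$beta - 1) < 1e-6) next
    S <- 1.2
    v0 <- as.numeric(modifier_velocity(S, 0, p))
    vinf <- p$beta * p$kcat * S / (p$alpha * p$Km + S)
    if (abs(v0 - vinf) < 1e-9 * v0) next
    x50 <- half_effect(S, p)
    vmid <- as.numeric(modifier_velocity(S, x50, p))
    expect_lt(abs(vmid - (v0 + vinf) / 2) / abs(vmid), 1e-9)
    root <- stats::uniroot(function(x) {
      as.numeric(modifier_velocity(S, x, p)) - (v0 + vinf) / 2
    }, c(1e-9 * p$KX, 1e9 * p$KX), tol = 1e-12 * p$KX)
    expect_rel_equal(x50, root$root, 1e-6)
  }
})

test_that("half-effect is undefined without modification", {
  p <- kinetic_params(kcat = 1, Km = 1, KX = 10, alpha = 1, beta = 1)
  expect_error(half_effect(1, p), "undefined midpoint")
})

test_that("SES law is unimodal with peak at sqrt(Km*Ksi)", {
  q <- ses_params(Vmax = 0.5, Km = 300, Ksi = 400)
  # Ksi -> Inf recovers MM
  qi <- ses_params(Vmax = 0.5, Km = 300, Ksi = Inf)
  pm <- kinetic_params(kcat = 0.5, Km = 300, KX = 1, alpha = 1, beta = 1,
                       conc_unit = "uM")
  S <- c(50, 300, 900)
  expect_equal(ses_velocity(S, qi), mm_velocity(S, pm))

  # brute-force argmax on a dense grid
  Sg <- seq(1, 2000, by = 0.5)
  v <- ses_velocity(Sg, q)
  expect_lt(abs(Sg[which.max(v)] - sqrt(300 * 400)), 1)
  # peak value
  Sstar <- sqrt(300 * 400)
  expect_equal(ses_velocity(Sstar, q),
               0.5 / (1 + 2 * sqrt(300 / 400)))
  # strictly decreasing beyond the peak
  post <- v[Sg > Sstar]
  expect_true(all(diff(post) < 0))
  expect_error(ses_params(Vmax = 1, Km = 1, Ksi = -2), "Ksi")
})

test_that("modifier-coupled SES law accentuates inhibition dose-dependently", {
  q <- ses_params(Vmax = 0.5, Km = 300, Ksi = 400, Kx = 0.1)
  S <- seq(100, 1000, by = 100)
  expect_equal(ses_modifier_velocity(S, 0, q), ses_velocity(S, q))
  # dv/dX < 0 by finite differences in the inhibited regime
  h <- 1e-6
  dv <- (ses_modifier_velocity(600, 0.16 + h, q) -
           ses_modifier_velocity(600, 0.16 - h, q)) / (2 * h)
  expect_lt(dv, 0)
  # X -> Inf kills the velocity for any S > 0
  expect_lt(ses_modifier_velocity(600, 1e12, q), 1e-9)
  # strictly decreasing in X at any fixed S > 0
  X <- seq(0, 0.32, by = 0.04)
  v <- ses_modifier_velocity(600, X, q)
  expect_true(all(diff(v) < 0))
  # missing coupling constant is an explicit error
  q0 <- ses_params(Vmax = 0.5, Km = 300, Ksi = 400)
  expect_error(ses_modifier_velocity(600, 0.1, q0), "Kx")
})

test_that("infinite alpha or KX routes to the flagged linear special case", {
  p <- kinetic_params(kcat = 2, Km = 1, KX = 10, alpha = Inf, beta = 0.5)
  expect_true(p$linear_case)
  v <- modifier_velocity(1, 5, p)
  expect_true(attr(v, "linear_case"))
  # matches classical competitive inhibition: v = kcat*S/(S + Km*(1+X/KX))
  expect_equal(as.numeric(v), 2 * 1 / (1 + 1 * (1 + 5 / 10)))
})
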