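test_that("the three reference substrate mechanisms are named correctly", {
  # Arg-pNA: strong specific (binding) inhibition with residual turnover
  m1 <- classify_mechanism(30.39, 0.09)
  expect_identical(m1$label, "hyperbolic predominantly specific inhibition")
  expect_identical(m1$specific_component, "inhibitory")
  expect_identical(m1$catalytic_component, "inhibitory")
  expect_identical(m1$dominance, "specific")

  # Ala-pNA: mixed activation dominated by catalytic turnover
  m2 <- classify_mechanism(0.82, 25.4)
  expect_identical(m2$label, "hyperbolic predominantly catalytic activation")
  expect_identical(m2$dominance, "catalytic")

  # Pro-pNA: alpha = beta, purely catalytic ("uncompetitive-like") activation
  m3 <- classify_mechanism(7.88, 7.88)
  expect_identical(m3$label, "hyperbolic catalytic activation")
  expect_identical(m3$specific_component, "absent")
})

test_that("dominance follows log-distance from neutrality", {
  expect_gt(abs(log(30.39)), abs(log(0.09)))
  expect_gt(abs(log(25.4)), abs(log(0.82)))
  # swapping distances flips dominance
  expect_identical(classify_mechanism(1.5, 0.09)$dominance, "catalytic")
  expect_identical(classify_mechanism(30, 0.5)$dominance, "specific")
})

test_that("labels for the reference triples are epsilon-robust", {
  for (eps in c(0.01, 0.02, 0.05, 0.08, 0.10)) {
    expect_identical(classify_mechanism(30.39, 0.09, eps)$label,
                     "hyperbolic predominantly specific inhibition")
    expect_identical(classify_mechanism(0.82, 25.4, eps)$label,
                     "hyperbolic predominantly catalytic activation")
    expect_identical(classify_mechanism(7.88, 7.88, eps)$label,
                     "hyperbolic catalytic activation")
  }
})

test_that("neutral coefficients give no modification", {
  expect_identical(classify_mechanism(1, 1)$label, "no modification")
  expect_identical(classify_mechanism(1.02, 0.99)$label, "no modification")
})

test_that("single-component mechanisms are labelled by their component", {
  expect_identical(classify_mechanism(5, 1)$label,
                   "hyperbolic specific inhibition")
  expect_identical(classify_mechanism(0.2, 1)$label,
                   "hyperbolic specific activation")
  expect_identical(classify_mechanism(1, 3)$label,
                   "hyperbolic catalytic activation")
  expect_identical(classify_mechanism(1, 0.3)$label,
                   "hyperbolic catalytic inhibition")
})

test_that("reciprocal coefficients swap inhibition and activation", {
  cases <- list(c(30.39, 0.09), c(5, 1), c(1, 3), c(8, 8))
  swap <- function(lbl) {
    tmp <- gsub("activation", "@@", lbl)
    tmp <- gsub("inhibition", "activation", tmp)
    gsub("@@", "inhibition", tmp)
  }
  for (ab in cases) {
    l1 <- classify_mechanism(ab[1], ab[2])$label
    l2 <- classify_mechanism(1 / ab[1], 1 / ab[2])$label
    expect_identical(l2, swap(l1))
  }
})

test_that("discordant components require a reference substrate level", {
  # alpha > 1 (specific inhibition) with beta > 1 (catalytic activation)
  expect_error(classify_mechanism(5, 2), "S_ref")
  m <- classify_mechanism(5, 2, S_ref = 1, Km = 1)
  # beta*(Km+S) - (alpha*Km+S) = 2*2 - 6 < 0: net inhibition
  expect_match(m$label, "inhibition")
  m2 <- classify_mechanism(5, 4.5, S_ref = 50, Km = 1)
  # 4.5*51 - 55 > 0: net activation at high S
  expect_match(m2$label, "activation")
})

test_that("beta = 0 is flagged as complete linear inhibition", {
  expect_warning(m <- classify_mechanism(2, 0), "linear")
  expect_identical(m$label, "complete (linear) catalytic inhibition")
  expect_true(m$linear_flag)
})

test_that("classification rejects out-of-range inputs", {
  expect_error(classify_mechanism(-1, 1), "alpha")
  expect_error(classify_mechanism(1, -1), "beta")
  expect_error(classify_mechanism(1, 1, epsilon = 0.7), "epsilon")
})
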