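test_that("global fit recovers all five parameters from noise-free grids", {
  truth <- arg_params()
  grid <- law_grid(truth, X = c(0, 10, 20, 40, 60, 80, 100))
  fit <- fit_modifier(grid)
  expect_rel_equal(coef(fit), c(24.35, 18.79, 50, 30.39, 0.09), 1e-3)
  expect_identical(fit$mechanism$label,
                   "hyperbolic predominantly specific inhibition")
})

test_that("an alpha = beta truth is recovered with unit ratio and the catalytic label", {
  truth <- pro_params()
  grid <- law_grid(truth, X = c(0, 100, 200, 400, 600, 800, 1000, 2000))
  fit <- fit_modifier(grid)
  expect_lt(abs(coef(fit)[["alpha"]] / coef(fit)[["beta"]] - 1), 1e-3)
  expect_identical(fit$mechanism$label, "hyperbolic catalytic activation")
})

test_that("the modifier-free design is rejected as non-identifiable", {
  truth <- ala_params()
  grid <- law_grid(truth, X = 0)
  expect_error(fit_modifier(grid), "non-identifiability|modifier levels")
})

test_that("weighted and unweighted fits agree on replicated noise-free data", {
  truth <- ala_params()
  grid <- law_grid(truth, X = c(0, 0.5, 1, 5, 10))
  grid <- grid[rep(seq_len(nrow(grid)), each = 2), ]
  grid$replicate <- rep(1:2, nrow(grid) / 2)
  f1 <- fit_modifier(grid, weights = "none")
  expect_rel_equal(coef(f1), unlist(truth[c("kcat", "Km", "KX", "alpha", "beta")]),
                   1e-3)
})

test_that("weak modifier coverage raises the poorly-determined flag", {
  # KX far above every design level: KX, alpha, beta barely identified
  truth <- kinetic_params(kcat = 2, Km = 1.5, KX = 5e4, alpha = 3, beta = 0.5)
  grid <- law_grid(truth, X = c(0, 1, 2, 4))
  set.seed(8)
  grid$v <- grid$v * (1 + rnorm(nrow(grid), 0, 0.02))
  fit <- fit_modifier(grid)
  expect_true(any(grepl("poorly_determined", fit$flags)))
})

test_that("modifier-fit methods are self-consistent", {
  truth <- ala_params()
  grid <- law_grid(truth, X = c(0, 0.5, 1, 5, 10))
  fit <- fit_modifier(grid)
  expect_equal(predict(fit), grid$v, tolerance = 1e-6)
  expect_equal(residuals(fit), grid$v - fitted(fit))
  p2 <- as_kinetic_params(fit)
  expect_s3_class(p2, "kinetic_params")
  expect_rel_equal(p2$kcat, truth$kcat, 1e-3)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$v, sims[[2]]$v))
  # deterministic under the same seed
  sims2 <- simulate(fit, nsim = 2, seed = 4)
  expect_identical(sims, sims2)
})

test_that("Monte-Carlo noise keeps well-identified parameters accurate and directions stable", {
  # replicate designs with 5% velocity CV, n = 6; assert the statistically
  # identifiable quantities (kcat under the Arg design, beta under the Ala
  # design) and that the net modification direction never flips.
  mc <- function(truth, X_levels, reps = 20) {
    out <- list(coefs = vector("list", reps), label = character(reps))
    for (i in seq_len(reps)) {
      grid <- expand.grid(S = c(0.5, 1, 2, 4, 8), X = X_levels)
      grid <- grid[rep(seq_len(nrow(grid)), each = 6), ]
      grid$replicate <- rep(1:6, length.out = nrow(grid))
      grid$v <- as.numeric(modifier_velocity(grid$S, grid$X, truth)) *
        (1 + rnorm(nrow(grid), 0, 0.05))
      fit <- fit_modifier(grid)
      out$coefs[[i]] <- coef(fit)
      out$label[i] <- fit$mechanism$label
    }
    out
  }
  set.seed(77)
  arg <- mc(arg_params(), c(0, 10, 20, 40, 60, 80, 100))
  ala <- mc(ala_params(), c(0, 0.1, 0.5, 1, 5, 10))
  arg_kcats <- vapply(arg$coefs, `[[`, 0, "kcat")
  ala_kcats <- vapply(ala$coefs, `[[`, 0, "kcat")
  expect_lt(median(abs(arg_kcats - 24.35) / 24.35), 0.15)
  expect_lt(median(abs(ala_kcats - 1.74) / 1.74), 0.15)
  # no direction flips: Arg stays an inhibition call, Ala an activation call
  expect_true(all(grepl("inhibition", arg$label)))
  expect_true(all(grepl("activation", ala$label)))
})
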