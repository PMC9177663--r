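test_that("standard curve recovers slope and intercept", {
  sc <- fit_standard_curve(c(0, 1, 2), c(0.0, 0.5, 1.0))
  expect_equal(sc$slope, 0.5)
  expect_equal(sc$intercept, 0.0)
  expect_equal(sc$r_squared, 1.0)

  sc2 <- fit_standard_curve(c(0, 1, 2), c(0.05, 0.55, 1.05))
  expect_equal(sc2$slope, 0.5)
  expect_equal(sc2$intercept, 0.05)

  # seeded 2% CV noise: slope within 5%
  set.seed(9)
  conc <- seq(0, 1, length.out = 8)
  sig <- (0.03 + 0.8 * conc) * (1 + rnorm(8, 0, 0.02))
  sc3 <- fit_standard_curve(conc, sig)
  expect_lt(abs(sc3$slope - 0.8) / 0.8, 0.05)

  expect_error(fit_standard_curve(c(0, 1), c(0, 1)), "3 distinct")
  expect_error(fit_standard_curve(c(1, 1, 1), c(0, 1, 2)), "3 distinct")
})

test_that("signal-to-product conversion round-trips and clips blanks", {
  sc <- flat_curve()
  conc <- c(0, 0.2, 0.7)
  sig <- 0.05 + 0.9 * conc
  expect_equal(as.numeric(signal_to_product(sc, sig)), conc)
  # blank signal maps to exactly zero
  expect_equal(as.numeric(signal_to_product(sc, 0.05)), 0)
  # small negative within 3 blank-SDs clips to 0 with a flag
  p <- signal_to_product(sc, 0.05 - 0.9 * 0.001, blank_sd = 0.9 * 0.001)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "clipped"))
  # large negative errors
  expect_error(signal_to_product(sc, -0.5), "below zero")
})

test_that("initial velocity is exact on a noise-free linear ramp", {
  sc <- flat_curve()
  times <- seq(0, 300, by = 10)
  v_true <- 1e-4                       # conc units per s
  pc <- list(times = times, signal = 0.05 + 0.9 * (v_true * times), S0 = 0.5)
  vp <- initial_velocity(pc, sc)
  expect_equal(vp$v, v_true, tolerance = 1e-9)
  expect_lte(vp$window_end_fraction, 0.10)
})

test_that("initial velocity window respects the consumption cap", {
  sc <- flat_curve()
  # fast ramp: 10% of S0 consumed after the 3rd of 8 reads
  times <- seq(0, 70, by = 10)
  S0 <- 0.1
  ramp <- 6e-4 * times                 # 10% of S0 reached at t = 16.7 s
  pc <- list(times = times, signal = 0.05 + 0.9 * ramp, S0 = S0)
  expect_error(initial_velocity(pc, sc, max_consumption = 0.10,
                                min_points = 5), "5 required")
  expect_error(initial_velocity(pc, sc, max_consumption = 0.5), "0.2")
})

test_that("windowed estimate tracks the analytic t = 0 slope under depletion", {
  # exponential approach: P(t) = S0*(1 - exp(-k t)) with v0 = k*S0
  sc <- flat_curve()
  S0 <- 0.5; k <- 2e-4
  times <- seq(0, 600, by = 10)
  P <- S0 * (1 - exp(-k * times))
  pc <- list(times = times, signal = 0.05 + 0.9 * P, S0 = S0)
  vp <- initial_velocity(pc, sc)
  expect_lt(abs(vp$v - k * S0) / (k * S0), 0.02)
})

test_that("velocity extraction is invariant to affine signal transforms", {
  set.seed(21)
  S0 <- 0.5; v_true <- 2e-4
  times <- seq(0, 400, by = 10)
  P <- v_true * times
  for (i in 1:5) {
    gain <- exp(runif(1, -1, 1)); offset <- runif(1, -0.2, 0.4)
    conc <- seq(0, 1, length.out = 6)
    sc_t <- fit_standard_curve(conc, offset + gain * conc)
    pc <- list(times = times, signal = offset + gain * P, S0 = S0)
    expect_equal(initial_velocity(pc, sc_t)$v, v_true, tolerance = 1e-8)
  }
})

test_that("endpoint velocities fit the early linear regime", {
  times <- c(300, 600, 900, 1200, 1800)
  expect_equal(as.numeric(endpoint_velocity(0.02 * times, times)), 0.02,
               tolerance = 1e-12)
  expect_error(endpoint_velocity(1, 100), ">= 3 stop points")
  # seeded noisy ramp within 5%
  set.seed(5)
  prod <- 0.02 * times * (1 + rnorm(5, 0, 0.02))
  expect_lt(abs(endpoint_velocity(prod, times) - 0.02) / 0.02, 0.05)
  # consumption cap excludes late stop points
  S0 <- 10
  prod2 <- c(0.3, 0.6, 0.9, 3, 8)      # last two exceed 10% of S0
  v <- endpoint_velocity(prod2, times, S0 = S0)
  expect_equal(attr(v, "n_points_used"), 3L)
})

test_that("plate and layout files round-trip through the readers", {
  tmp <- withr::local_tempdir()
  plate <- data.frame(well = rep(c("A1", "A2"), each = 6),
                      time_s = rep(seq(0, 50, 10), 2),
                      signal = 0.05 + 0.9 * c(1e-4 * seq(0, 50, 10),
                                              2e-4 * seq(0, 50, 10)))
  layout <- data.frame(well = c("A1", "A2"), substrate = "Ala-pNA",
                       S0 = c(0.5, 1), S_unit = "mM",
                       X = c(0, 10), X_unit = "uM", replicate = 1L)
  pf <- file.path(tmp, "plate.csv"); lf <- file.path(tmp, "layout.csv")
  write.csv(plate, pf, row.names = FALSE)
  write.csv(layout, lf, row.names = FALSE)
  curves <- read_plate_data(pf, lf)
  expect_length(curves, 2)
  vel <- extract_velocities(curves, flat_curve())
  expect_equal(sort(vel$v), c(1e-4, 2e-4), tolerance = 1e-8)
  # missing layout row is an explicit error
  write.csv(layout[1, ], lf, row.names = FALSE)
  expect_error(read_plate_data(pf, lf), "absent from layout")
})
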