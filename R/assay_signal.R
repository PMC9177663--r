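#' Fit a linear standard curve
#'
#' Ordinary least-squares line `signal = intercept + slope * concentration`,
#' the calibration used to convert chromogenic (p-nitroaniline A405) or
#' fluorescent (Gly-Pro/fluorescamine) readings into product concentration.
#'
#' @param concentrations Known standard concentrations (>= 3 distinct
#'   values, spanning or including a blank).
#' @param signals Measured signals, same length.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `resid_sd` (signal units), `n`.
#' @export
fit_standard_curve <- function(concentrations, signals) {
  if (length(concentrations) != length(signals)) {
    stop("'concentrations' and 'signals' must have equal length")
  }
  if (length(unique(concentrations)) < 3) {
    stop("a standard curve needs >= 3 distinct concentrations")
  }
  if (stats::sd(concentrations) == 0) stop("zero concentration spread")
  fit <- stats::lm(signals ~ concentrations)
  sl <- unname(stats::coef(fit)[2])
  if (!is.finite(sl) || sl <= 0) {
    stop("standard-curve slope must be positive; got ", format(sl))
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = sl, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, resid_sd = stats::sigma(fit),
         n = length(signals)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: signal = %.5g + %.5g * conc  (r^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Convert signal to product concentration via a standard curve
#'
#' Inverts the calibration line: `(signal - intercept) / slope`. Small
#' negative concentrations within 3 standard deviations of the blank are
#' clipped to zero (attribute `clipped` marks which); larger negatives
#' indicate a calibration problem and raise an error.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param signal Numeric signal vector.
#' @param blank_sd Standard deviation of a blank read, in signal units;
#'   defaults to the calibration residual SD. Callers with access to the
#'   trace itself (e.g. [initial_velocity()]) pass a read-noise estimate.
#' @return Product concentrations (standard-curve concentration unit), with
#'   logical attribute `clipped`.
#' @export
signal_to_product <- function(curve, signal, blank_sd = curve$resid_sd) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- (signal - curve$intercept) / curve$slope
  # tolerance: 3 sigma of the blank in concentration units (plus a numeric
  # floor for noise-free synthetic curves)
  tol <- max(3 * blank_sd / curve$slope, 1e-9 * max(abs(conc), 1))
  bad <- conc < -tol
  if (any(bad)) {
    stop(sprintf(
      "%d signal(s) fall more than 3 blank-SDs below zero concentration (min = %.4g)",
      sum(bad), min(conc)))
  }
  clipped <- conc < 0
  conc[clipped] <- 0
  attr(conc, "clipped") <- clipped
  conc
}

#' Extract the initial velocity from a progress curve
#'
#' Converts the raw signal to product concentration, truncates the series at
#' the last read where fractional substrate consumption (`product / S0`)
#' stays at or below `max_consumption`, and returns a least-squares estimate
#' of the initial slope of product versus time over that window — the
#' standard initial-rate criterion for plate-reader kinetics.
#'
#' Even within a 10%-consumption window the velocity declines measurably as
#' substrate depletes (by up to `max_consumption * Km/(Km + S0)` of itself),
#' so the plain linear slope underestimates the true initial rate by a few
#' percent when `S0 << Km`. The default `degree = 2` therefore fits a
#' quadratic in time and reports its derivative at t = 0, which removes the
#' first-order depletion bias; `degree = 1` gives the uncorrected linear
#' slope.
#'
#' @param pc A progress curve: list or data.frame with `times` (s, strictly
#'   increasing, >= 5 reads), `signal`, `S0` (initial substrate
#'   concentration in the standard-curve unit), optional `X`, `well_id`,
#'   `replicate`.
#' @param curve A [fit_standard_curve()] object.
#' @param max_consumption Largest tolerated consumed fraction of `S0` in
#'   the fitting window; in (0, 0.2]. Default 0.10.
#' @param min_points Minimum reads required in the window. Default 5.
#' @param degree Polynomial degree of the windowed product-vs-time model;
#'   the reported velocity is the fitted derivative at t = 0. Default 2.
#' @return Object of class `velocity_point`: `S0`, `X`, `v` (conc/s),
#'   `n_points_used`, `window_end_fraction`, `flags` (character vector;
#'   "non_monotone" when the windowed trend decreases beyond noise).
#' @export
initial_velocity <- function(pc, curve, max_consumption = 0.10,
                             min_points = 5, degree = 2) {
  stopifnot(inherits(curve, "standard_curve"))
  if (max_consumption <= 0 || max_consumption > 0.2) {
    stop("'max_consumption' must lie in (0, 0.2]")
  }
  times <- pc$times; signal <- pc$signal
  if (length(times) < 5) stop("progress curve needs >= 5 time points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(times < 0)) stop("'times' must be nonnegative")
  if (length(signal) != length(times)) {
    stop("'signal' and 'times' lengths differ")
  }
  if (is.null(pc$S0) || pc$S0 <= 0) stop("'S0' must be a positive concentration")

  # read-noise scale from successive differences (robust to the ramp)
  read_sd <- stats::mad(diff(signal)) / sqrt(2)
  product <- signal_to_product(curve, signal,
                               blank_sd = max(curve$resid_sd, read_sd))
  frac <- product / pc$S0
  ok <- frac <= max_consumption
  # truncate at the first violation (later reads are outside the window
  # even if noise dips them back under the cap)
  cut <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
  if (cut < min_points) {
    stop(sprintf(
      "only %d read(s) before %.0f%% consumption; %d required",
      cut, 100 * max_consumption, min_points))
  }
  if (!degree %in% c(1, 2)) stop("'degree' must be 1 or 2")
  w <- seq_len(cut)
  tw <- times[w]; pw <- product[w]
  fit <- if (degree == 2 && cut >= max(min_points, 4)) {
    stats::lm(pw ~ tw + I(tw^2))
  } else {
    stats::lm(pw ~ tw)
  }
  v <- unname(stats::coef(fit)[2])   # derivative at t = 0 either way
  flags <- character(0)
  # a negative trend beyond noise means the window is not an initial-rate
  # regime; flag rather than silently report the slope
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  if (is.finite(se) && v < -3 * se) flags <- c(flags, "non_monotone")
  if (!is.finite(v)) stop("initial-velocity fit returned a non-finite slope")
  structure(
    list(well_id = pc$well_id %||% NA_character_,
         S0 = pc$S0, X = pc$X %||% NA_real_,
         replicate = pc$replicate %||% NA_integer_,
         v = v, n_points_used = cut,
         window_end_fraction = frac[cut], flags = flags),
    class = "velocity_point"
  )
}

#' @export
print.velocity_point <- function(x, ...) {
  cat(sprintf("v = %.6g conc/s  (S0 = %g, X = %g, %d reads, %.1f%% consumed%s)\n",
              x$v, x$S0, x$X, x$n_points_used,
              100 * x$window_end_fraction,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Velocity from endpoint (stopped-reaction) product measurements
#'
#' For assays where reactions are quenched at several stop times and product
#' is quantified afterwards (e.g. Gly-Pro by fluorescamine derivatization):
#' the least-squares slope of product concentration versus stop time over
#' the early linear regime.
#'
#' @param product_concs Product concentrations at the stop times.
#' @param times Stop times, s; >= 3 points, strictly increasing.
#' @param S0 Initial substrate concentration; when given, stop points beyond
#'   `max_consumption * S0` are excluded.
#' @param max_consumption As in [initial_velocity()].
#' @return Velocity (conc/s) with attribute `n_points_used`.
#' @export
endpoint_velocity <- function(product_concs, times, S0 = NULL,
                              max_consumption = 0.10) {
  if (length(times) < 3) stop("endpoint velocity needs >= 3 stop points")
  if (length(product_concs) != length(times)) {
    stop("'product_concs' and 'times' lengths differ")
  }
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  keep <- rep(TRUE, length(times))
  if (!is.null(S0)) {
    ok <- product_concs / S0 <= max_consumption
    cut <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
    if (cut < 3) stop("fewer than 3 stop points within the consumption cap")
    keep <- seq_along(times) <= cut
  }
  fit <- stats::lm(product_concs[keep] ~ times[keep])
  v <- unname(stats::coef(fit)[2])
  if (!is.finite(v)) stop("endpoint-velocity fit returned a non-finite slope")
  attr(v, "n_points_used") <- sum(keep)
  v
}

#' Extract velocities from a set of progress curves
#'
#' Applies [initial_velocity()] to every curve and assembles the long-format
#' velocity table consumed by the fitting functions. Velocities are divided
#' by `Etot` when it is supplied, yielding normalized v/Etot in s^-1.
#'
#' @param curves List of progress curves (see [initial_velocity()]), e.g.
#'   from [generate_progress_curves()] or [read_plate_data()].
#' @param curve A [fit_standard_curve()] object.
#' @param Etot Total enzyme concentration in the substrate unit (optional).
#' @param ... Passed to [initial_velocity()].
#' @return data.frame with columns `well`, `S`, `X`, `replicate`, `v`,
#'   `n_points`, `flags`.
#' @export
extract_velocities <- function(curves, curve, Etot = NULL, ...) {
  rows <- lapply(curves, function(pc) {
    vp <- initial_velocity(pc, curve, ...)
    data.frame(well = vp$well_id, S = vp$S0, X = vp$X,
               replicate = vp$replicate,
               v = if (is.null(Etot)) vp$v else vp$v / Etot,
               n_points = vp$n_points_used,
               flags = paste(vp$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "normalized") <- !is.null(Etot)
  out
}

#' Read long-format plate data plus a layout file
#'
#' The plate file is a CSV with header `well,time_s,signal`; the layout CSV
#' maps wells to conditions with header
#' `well,substrate,S0,S_unit,X,X_unit,replicate`. Returns the list of
#' progress curves used by [extract_velocities()].
#'
#' @param plate_path,layout_path CSV file paths.
#' @return List of progress curves with attributes `S_unit`, `X_unit`,
#'   `substrate`.
#' @export
read_plate_data <- function(plate_path, layout_path) {
  plate <- utils::read.csv(plate_path, stringsAsFactors = FALSE)
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
  need <- c("well", "time_s", "signal")
  if (!all(need %in% names(plate))) {
    stop("plate file must have columns: ", paste(need, collapse = ", "))
  }
  needl <- c("well", "substrate", "S0", "S_unit", "X", "X_unit", "replicate")
  if (!all(needl %in% names(layout))) {
    stop("layout file must have columns: ", paste(needl, collapse = ", "))
  }
  missing_wells <- setdiff(unique(plate$well), layout$well)
  if (length(missing_wells)) {
    stop("wells absent from layout: ", paste(missing_wells, collapse = ", "))
  }
  curves <- lapply(split(plate, plate$well), function(d) {
    d <- d[order(d$time_s), ]
    lay <- layout[match(d$well[1], layout$well), ]
    list(well_id = d$well[1], times = d$time_s, signal = d$signal,
         S0 = lay$S0, X = lay$X, replicate = lay$replicate,
         substrate = lay$substrate)
  })
  attr(curves, "S_unit") <- layout$S_unit[1]
  attr(curves, "X_unit") <- layout$X_unit[1]
  attr(curves, "substrate") <- layout$substrate[1]
  curves
}

#' Write a velocity table to CSV
#'
#' @param velocities data.frame from [extract_velocities()] or
#'   [generate_velocity_grid()].
#' @param path Output CSV path.
#' @param substrate,unit Optional annotation columns.
#' @return `path`, invisibly.
#' @export
write_velocity_csv <- function(velocities, path, substrate = NA, unit = NA) {
  out <- velocities
  if (!is.na(substrate)) out$substrate <- substrate
  if (!is.na(unit)) out$unit <- unit
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
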