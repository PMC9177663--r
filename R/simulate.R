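#' Reference plate-assay designs
#'
#' The four assay layouts the package emulates, matching the published assay
#' conditions for LTA4H aminopeptidase kinetics: three chromogenic
#' p-nitroanilide (pNA) substrate designs (Arg-, Ala-, Pro-pNA; substrate
#' doubling series 0.5--8.0 mM, substrate-specific 4MDM grids, six
#' replicates, continuous A405 reads every 10 s for 30 min) and the PGP
#' design (substrate 100--1000 uM, modifier 0--0.32 uM, twenty replicates,
#' stopped-reaction endpoints read by fluorescamine derivatization).
#' Velocity noise is multiplicative with a 5% coefficient of variation.
#'
#' Enzyme concentrations follow the assay recipes: 10 ug/mL LTA4H
#' (MW 69.3 kDa) for the pNA assays and 31.25 ng/mL for the PGP assay.
#'
#' @return Named list of `assay_design` objects:
#'   `arg_pna`, `ala_pna`, `pro_pna`, `pgp`.
#' @export
assay_designs <- function() {
  pna <- function(substrate, X_levels) {
    structure(
      list(substrate = substrate,
           S_levels = c(0.5, 1, 2, 4, 8), conc_unit = "mM",
           X_levels = X_levels, mod_unit = "uM",
           replicates = 6L,
           read_interval = 10, duration = 1800,
           Etot = 10e-3 / 69300 * 1e3,   # 10 ug/mL over 69.3 kDa, in mM
           noise_cv = 0.05,
           read_noise_cv = 0.005,
           endpoint = FALSE, stop_times = NULL),
      class = "assay_design"
    )
  }
  pgp <- structure(
    list(substrate = "PGP",
         S_levels = seq(100, 1000, by = 100), conc_unit = "uM",
         X_levels = c(0, 0.04, 0.08, 0.16, 0.32), mod_unit = "uM",
         replicates = 20L,
         read_interval = NA_real_, duration = 1800,
         Etot = 31.25e-6 / 69300 * 1e6,  # 31.25 ng/mL over 69.3 kDa, in uM
         noise_cv = 0.05,
         endpoint = TRUE, stop_times = c(300, 600, 900, 1200, 1800)),
    class = "assay_design"
  )
  list(
    arg_pna = pna("Arg-pNA", c(0, 10, 20, 40, 60, 80, 100)),
    ala_pna = pna("Ala-pNA", c(0, 0.1, 0.5, 1, 5, 10)),
    pro_pna = pna("Pro-pNA", c(0, 100, 200, 400, 600, 800, 1000, 2000)),
    pgp = pgp
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("Assay design: %s (%s)\n", x$substrate,
              if (x$endpoint) "endpoint" else "continuous"))
  cat(sprintf("  S: %s %s   X: %s %s\n",
              paste(x$S_levels, collapse = ", "), x$conc_unit,
              paste(x$X_levels, collapse = ", "), x$mod_unit))
  cat(sprintf("  replicates: %d   noise CV: %g   Etot: %.4g %s\n",
              x$replicates, x$noise_cv, x$Etot, x$conc_unit))
  invisible(x)
}

#' Reference kinetic parameter sets for simulation
#'
#' Generating truths for the three pNA substrates, using the reported
#' turnover/affinity/coupling constants for 4MDM modulation of LTA4H
#' aminopeptidase activity (kcat and Km from the zero-modifier condition;
#' alpha and beta from the global mechanism fits). The modifier dissociation
#' constant KX is not derivable from those tables and is set to a round
#' 50 uM simulation default. The PGP set is a synthetic SES parameterization
#' (Vmax 0.5 s^-1, Km 300 uM, Ksi 400 uM, Kx 0.1 uM) placing the velocity
#' peak at sqrt(Km*Ksi) ~ 346 uM, inside the 100--1000 uM design range.
#'
#' @return Named list: `arg_pna`, `ala_pna`, `pro_pna`
#'   ([kinetic_params()]) and `pgp` ([ses_params()]).
#' @export
reference_parameters <- function() {
  list(
    arg_pna = kinetic_params(kcat = 24.35, Km = 18.79, KX = 50,
                             alpha = 30.39, beta = 0.09,
                             Etot = 10e-3 / 69300 * 1e3,
                             conc_unit = "mM", mod_unit = "uM"),
    ala_pna = kinetic_params(kcat = 1.74, Km = 1.60, KX = 50,
                             alpha = 0.82, beta = 25.4,
                             Etot = 10e-3 / 69300 * 1e3,
                             conc_unit = "mM", mod_unit = "uM"),
    pro_pna = kinetic_params(kcat = 0.19, Km = 0.84, KX = 50,
                             alpha = 7.88, beta = 7.88,
                             Etot = 10e-3 / 69300 * 1e3,
                             conc_unit = "mM", mod_unit = "uM"),
    pgp = ses_params(Vmax = 0.5, Km = 300, Ksi = 400, Kx = 0.1,
                     conc_unit = "uM", mod_unit = "uM")
  )
}

#' Simulate a velocity grid from a design and a generating truth
#'
#' Evaluates the appropriate rate law ([modifier_velocity()] for
#' `kinetic_params` truths, [ses_modifier_velocity()] /
#' [ses_velocity()] for `ses_params`) on the design's (S, X) grid and adds
#' independent multiplicative Gaussian noise
#' `v_obs = v_true * (1 + e)`, `e ~ N(0, noise_cv^2)` truncated at
#' 4 standard deviations so signals stay positive. Deterministic under a
#' fixed seed.
#'
#' @param design An [assay_designs()] entry (or compatible list).
#' @param truth [kinetic_params()] or [ses_params()] generating values;
#'   units must match the design.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame (`S`, `X`, `replicate`, `v`) of normalized velocities
#'   (v/Etot, s^-1) with attributes `conc_unit`, `mod_unit`, `Etot`,
#'   `truth`.
#' @export
generate_velocity_grid <- function(design, truth, seed = NULL) {
  check_design_units(design, truth)
  withr_seed(seed)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      X = design$X_levels, S = design$S_levels)
  grid <- grid[, c("S", "X", "replicate")]
  v_true <- eval_law(grid$S, grid$X, truth)
  eps <- truncnorm_pm4(length(v_true), design$noise_cv)
  grid$v <- v_true * (1 + eps)
  rownames(grid) <- NULL
  attr(grid, "conc_unit") <- design$conc_unit
  attr(grid, "mod_unit") <- design$mod_unit
  attr(grid, "Etot") <- design$Etot
  attr(grid, "truth") <- truth
  grid
}

#' Simulate raw progress curves with substrate depletion
#'
#' Integrates `dP/dt = Etot * law(S0 - P, X)` for each well — substrate
#' depletion included, so the initial-velocity window logic downstream is
#' genuinely exercised — maps product to signal through the standard curve,
#' and adds multiplicative read noise. The `t -> 0` slope of the noise-free
#' product trace equals `Etot * law(S0, X)`.
#'
#' @param design An [assay_designs()] entry with a finite `read_interval`.
#' @param truth Generating [kinetic_params()] or [ses_params()].
#' @param curve A [fit_standard_curve()] object mapping product
#'   concentration (design conc unit) to signal.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param noise_cv Per-read noise CV. Defaults to the design's
#'   `read_noise_cv` (0.5%, typical plate-reader photometric precision) —
#'   distinct from the design's velocity-replicate CV (`noise_cv`, 5%),
#'   which describes scatter of extracted velocities, not of single reads.
#' @return List of progress curves (`well_id`, `times`, `signal`, `S0`,
#'   `X`, `replicate`) with units attached as attributes.
#' @export
generate_progress_curves <- function(design, truth, curve, seed = NULL,
                                     noise_cv = design$read_noise_cv %||%
                                       design$noise_cv) {
  stopifnot(inherits(curve, "standard_curve"))
  check_design_units(design, truth)
  if (!is.finite(design$read_interval)) {
    stop("design has no read interval: use endpoint simulation instead")
  }
  times <- seq(0, design$duration, by = design$read_interval)
  if (length(times) < 5) stop("duration too short for >= 5 reads")
  withr_seed(seed)
  wells <- expand.grid(replicate = seq_len(design$replicates),
                       X = design$X_levels, S = design$S_levels)
  out <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    S0 <- wells$S[i]; X <- wells$X[i]
    dP <- function(t, y, parms) {
      list(design$Etot * eval_law(max(S0 - y[1], 0), X, truth))
    }
    sol <- deSolve::ode(c(P = 0), times, dP, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12 * S0)
    P <- sol[, "P"]
    signal <- curve$intercept + curve$slope * P
    if (noise_cv > 0) {
      signal <- signal * (1 + truncnorm_pm4(length(signal), noise_cv))
    }
    out[[i]] <- list(well_id = sprintf("W%03d", i), times = times,
                     signal = signal, S0 = S0, X = X,
                     replicate = wells$replicate[i])
  }
  attr(out, "S_unit") <- design$conc_unit
  attr(out, "X_unit") <- design$mod_unit
  attr(out, "substrate") <- design$substrate
  out
}

#' Write simulated progress curves as the plate + layout CSV pair
#'
#' Produces exactly the long-format files [read_plate_data()] consumes, so
#' simulation and analysis close the loop through the file interface.
#'
#' @param curves Output of [generate_progress_curves()].
#' @param plate_path,layout_path Output CSV paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_plate_files <- function(curves, plate_path, layout_path) {
  plate <- do.call(rbind, lapply(curves, function(pc) {
    data.frame(well = pc$well_id, time_s = pc$times, signal = pc$signal)
  }))
  layout <- do.call(rbind, lapply(curves, function(pc) {
    data.frame(well = pc$well_id,
               substrate = attr(curves, "substrate") %||% NA_character_,
               S0 = pc$S0, S_unit = attr(curves, "S_unit") %||% NA_character_,
               X = pc$X, X_unit = attr(curves, "X_unit") %||% NA_character_,
               replicate = pc$replicate)
  }))
  utils::write.csv(plate, plate_path, row.names = FALSE)
  utils::write.csv(layout, layout_path, row.names = FALSE)
  invisible(c(plate = plate_path, layout = layout_path))
}

# internal: pick the rate law matching the truth class
eval_law <- function(S, X, truth) {
  if (inherits(truth, "kinetic_params")) {
    as.numeric(modifier_velocity(S, X, truth))
  } else if (inherits(truth, "ses_params")) {
    if (is.na(truth$Kx)) {
      if (any(X > 0)) stop("SES truth has no 'Kx' but design has X > 0")
      ses_velocity(S, truth)
    } else {
      ses_modifier_velocity(S, X, truth)
    }
  } else {
    stop("'truth' must be kinetic_params or ses_params")
  }
}

check_design_units <- function(design, truth) {
  tu <- truth$conc_unit
  if (!identical(design$conc_unit, tu)) {
    stop(sprintf("unit mismatch: design substrate unit '%s' vs truth '%s'",
                 design$conc_unit, tu))
  }
  if (!identical(design$mod_unit, truth$mod_unit)) {
    stop(sprintf("unit mismatch: design modifier unit '%s' vs truth '%s'",
                 design$mod_unit, truth$mod_unit))
  }
  invisible(TRUE)
}

# internal: N(0, cv^2) truncated (clipped) at +/- 4 sd
truncnorm_pm4 <- function(n, cv) {
  if (cv == 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, cv), -4 * cv), 4 * cv)
}

# internal: set the seed for the calling function's body, restoring the
# caller-visible RNG state when that function exits
withr_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  restore <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    bquote(assign(".Random.seed", .(get(".Random.seed", envir = globalenv())),
                  envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}
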