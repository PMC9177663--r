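#' Catalytic-efficiency table from a Michaelis--Menten family
#'
#' One row per modifier level: kcat and Km with standard errors and the
#' catalytic efficiency kcat/Km. The efficiency is always recomputed from
#' the (unrounded) estimates, never stored; rounding happens only at
#' serialization via [format_efficiency_table()].
#'
#' @param fits A `mm_family` from [fit_mm_family()], or a list of `mm_fit`.
#' @return data.frame with columns `X`, `kcat`, `kcat_se`, `Km`, `Km_se`,
#'   `efficiency`.
#' @export
efficiency_table <- function(fits) {
  if (inherits(fits, "mm_family")) fits <- fits$fits
  if (!length(fits)) stop("'fits' is empty")
  rows <- lapply(fits, function(f) {
    co <- coef(f)
    data.frame(X = f$X, kcat = co[["kcat"]], kcat_se = f$se[["kcat"]],
               Km = co[["Km"]], Km_se = f$se[["Km"]],
               efficiency = co[["kcat"]] / co[["Km"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$X), , drop = FALSE]
}

#' Render an efficiency table for publication-style output
#'
#' Two-decimal presentation (the convention of kinetic summary tables);
#' full precision is retained in the numeric table and JSON outputs.
#'
#' @param tab data.frame from [efficiency_table()].
#' @param digits Decimal places. Default 2.
#' @return data.frame of character columns `X`, `kcat`, `Km`, `efficiency`
#'   with "estimate +/- SE" formatting.
#' @export
format_efficiency_table <- function(tab, digits = 2) {
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  data.frame(
    X = format(tab$X, trim = TRUE),
    kcat = paste0(fmt(tab$kcat), " ± ", fmt(tab$kcat_se)),
    Km = paste0(fmt(tab$Km), " ± ", fmt(tab$Km_se)),
    efficiency = fmt(tab$efficiency),
    stringsAsFactors = FALSE
  )
}

#' Simulate a named plate assay to files
#'
#' Config-driven front end over [generate_progress_curves()] /
#' [generate_velocity_grid()]: simulates one of the [assay_designs()] with
#' a [reference_parameters()] truth (or explicit parameter values) and
#' writes the plate + layout CSV pair (continuous designs) or a velocity
#' CSV (endpoint designs), plus a JSON manifest recording the seed, design
#' and package version.
#'
#' @param config A list or path to a YAML file with elements: `design`
#'   (one of "arg_pna", "ala_pna", "pro_pna", "pgp"), `seed` (integer),
#'   `out_dir`, optional `truth` (named list overriding the reference
#'   parameter values), optional `standard_curve` (list with `slope`,
#'   `intercept`).
#' @return Named character vector of written files, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config)
  for (f in c("design", "seed", "out_dir")) {
    if (is.null(cfg[[f]])) stop("config is missing '", f, "'")
  }
  designs <- assay_designs()
  if (!cfg$design %in% names(designs)) {
    stop("unknown design '", cfg$design, "'; available: ",
         paste(names(designs), collapse = ", "))
  }
  design <- designs[[cfg$design]]
  truth <- config_truth(cfg, design)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- character(0)
  if (design$endpoint) {
    grid <- generate_velocity_grid(design, truth, seed = cfg$seed)
    path <- file.path(cfg$out_dir, "velocities.csv")
    write_velocity_csv(grid, path, substrate = design$substrate,
                       unit = "1/s")
    files["velocities"] <- path
  } else {
    sc <- config_standard_curve(cfg)
    curves <- generate_progress_curves(design, truth, sc, seed = cfg$seed)
    paths <- write_plate_files(curves,
                               file.path(cfg$out_dir, "plate.csv"),
                               file.path(cfg$out_dir, "layout.csv"))
    files <- paths
  }
  manifest <- list(design = cfg$design, seed = cfg$seed,
                   truth = unclass(truth),
                   package = "modkin",
                   version = as.character(utils::packageVersion("modkin")),
                   files = as.list(files))
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["manifest"] <- mpath
  invisible(files)
}

#' Run the full analysis pipeline to files
#'
#' signal -> velocities -> per-level Michaelis--Menten family -> global
#' modifier fit -> mechanism classification (-> dose--response when the
#' config names a fixed substrate level). Writes the efficiency table CSV,
#' a parameter JSON carrying estimates, standard errors and the mechanism
#' label, and the velocity CSV.
#'
#' @param config A list or YAML path with elements: `plate`, `layout`
#'   (input CSVs), `out_dir`, optional `standard_curve` (`slope`,
#'   `intercept`), `Etot` (for velocity normalization; defaults per the
#'   pNA assay recipe), `max_consumption`, `min_points`, `epsilon`,
#'   `dose_response_S` (fixed S for a velocity-vs-X fit).
#' @return Named character vector of written files, invisibly.
#' @export
run_analyze <- function(config) {
  cfg <- load_config(config)
  for (f in c("plate", "layout", "out_dir")) {
    if (is.null(cfg[[f]])) stop("config is missing '", f, "'")
  }
  for (f in c("plate", "layout")) {
    if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config_standard_curve(cfg)
  Etot <- cfg$Etot %||% (10e-3 / 69300 * 1e3)
  curves <- read_plate_data(cfg$plate, cfg$layout)
  vel <- extract_velocities(curves, sc, Etot = Etot,
                            max_consumption = cfg$max_consumption %||% 0.10,
                            min_points = cfg$min_points %||% 5)
  files <- character(0)
  vpath <- file.path(cfg$out_dir, "velocities.csv")
  write_velocity_csv(vel, vpath, substrate = attr(curves, "substrate"),
                     unit = "1/s")
  files["velocities"] <- vpath

  fam <- fit_mm_family(vel)
  tab <- efficiency_table(fam)
  tpath <- file.path(cfg$out_dir, "efficiency_table.csv")
  utils::write.csv(format_efficiency_table(tab), tpath, row.names = FALSE)
  utils::write.csv(tab, file.path(cfg$out_dir, "efficiency_table_full.csv"),
                   row.names = FALSE)
  files["efficiency_table"] <- tpath

  fit <- fit_modifier(vel, epsilon = cfg$epsilon %||% 0.05)
  out <- list(schema = "modkin/modifier_fit/1",
              parameters = as.list(fit$coefficients),
              standard_errors = as.list(fit$se),
              mechanism = fit$mechanism$label,
              mechanism_detail = unclass(fit$mechanism),
              rss = fit$rss, n = fit$n, flags = fit$flags)
  jpath <- file.path(cfg$out_dir, "modifier_fit.json")
  jsonlite::write_json(out, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["modifier_fit"] <- jpath

  if (!is.null(cfg$dose_response_S)) {
    # derived view: titrate the fitted law over a log range bracketing the
    # analytic midpoint at the requested substrate level
    p <- as_kinetic_params(fit)
    x50 <- half_effect(cfg$dose_response_S, p)
    Xg <- c(0, x50 * 10^seq(-2, 2, length.out = 11))
    dr_data <- data.frame(X = Xg,
                          v = as.numeric(modifier_velocity(
                            cfg$dose_response_S, Xg, p)))
    dr <- tryCatch(fit_dose_response(dr_data, S_fixed = cfg$dose_response_S),
                   error = function(e) e)
    if (!inherits(dr, "error")) {
      drj <- list(schema = "modkin/dose_response/1",
                  S_fixed = dr$S_fixed, direction = dr$direction,
                  label = dr$label, coefficients = as.list(dr$coefficients))
      dpath <- file.path(cfg$out_dir, "dose_response.json")
      jsonlite::write_json(drj, dpath, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      files["dose_response"] <- dpath
    }
  }
  invisible(files)
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("'config' must be a list or a YAML file path")
  }
}

config_truth <- function(cfg, design) {
  ref <- reference_parameters()
  if (is.null(cfg$truth)) return(ref[[cfg$design]])
  tr <- cfg$truth
  if (design$endpoint) {
    ses_params(tr$Vmax, tr$Km, tr$Ksi, Kx = tr$Kx %||% NA_real_,
               conc_unit = design$conc_unit, mod_unit = design$mod_unit)
  } else {
    kinetic_params(tr$kcat, tr$Km, tr$KX, tr$alpha, tr$beta,
                   Etot = design$Etot,
                   conc_unit = design$conc_unit, mod_unit = design$mod_unit)
  }
}

# default chromogenic calibration: a plausible A405 response for
# p-nitroaniline in a 200 uL microplate well (signal per conc unit)
config_standard_curve <- function(cfg) {
  sc <- cfg$standard_curve
  slope <- sc$slope %||% 1.0
  intercept <- sc$intercept %||% 0.04
  conc <- seq(0, 0.5, length.out = 6)
  fit_standard_curve(conc, intercept + slope * conc)
}
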