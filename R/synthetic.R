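# Synthetic dual-fluid SMR experiments: ground-truth cell populations plus
# noisy paired buoyant-mass records with the statistical structure the
# analysis assumes (lognormal dry masses, configurable density and
# water-fraction spread, empirical-scale measurement noise, optional
# incomplete water exchange decaying with exposure time).

#' Scenario configuration for a synthetic SMR experiment
#'
#' @param n_cells Number of cells.
#' @param dry_mass_median Median dry mass, fg (lognormal distribution).
#' @param dry_mass_cv Coefficient of variation of dry mass.
#' @param dry_density_mean Mean dry density, g/cm3.
#' @param dry_density_cv CV of dry density (0 = homogeneous population, the
#'   null-model assumption).
#' @param water_fraction_mean Mean intracellular water fraction of total
#'   volume, in (0, 0.99).
#' @param water_fraction_cv CV of the water fraction (draws truncated to
#'   (0.01, 0.99)).
#' @param fluid1,fluid2 The measurement [fluid_spec] pair. The default is
#'   the PBS pair under the neutral-water idealization
#'   (`smr_fluids(water_neutral = TRUE)`), i.e. exchange renders the
#'   intracellular water exactly neutrally buoyant, matching the assumption
#'   of the inversion; pass fluids with pure-fluid water densities to
#'   simulate the residual PBS bias instead.
#' @param noise_scale Single-measurement buoyant-mass error SD, fg.
#' @param exchange_time_constant Time constant (s) of H2O->D2O exchange in
#'   the second fluid; 0 means instantaneous (complete) exchange.
#' @param exposure_time_range Uniform range (s) of times between the two
#'   weighings; the two measurements are made several seconds apart.
#' @param seed Integer seed; all generator output is deterministic given it.
#' @return Object of class `"scenario_config"` (a validated list).
#' @export
scenario_config <- function(n_cells = 500L,
                            dry_mass_median = 203,
                            dry_mass_cv = 0.35,
                            dry_density_mean = 1.40,
                            dry_density_cv = 0,
                            water_fraction_mean = 0.78,
                            water_fraction_cv = 0,
                            fluid1 = smr_fluids(water_neutral = TRUE)$h2o_pbs,
                            fluid2 = smr_fluids(water_neutral = TRUE)$d2o_pbs,
                            noise_scale = 0.5,
                            exchange_time_constant = 0,
                            exposure_time_range = c(1, 30),
                            seed = 1L) {
  stopifnot(n_cells >= 1, dry_mass_median > 0, dry_mass_cv >= 0,
            dry_density_mean > 0, dry_density_cv >= 0,
            noise_scale >= 0, exchange_time_constant >= 0,
            length(exposure_time_range) == 2L,
            exposure_time_range[1] >= 0,
            exposure_time_range[2] >= exposure_time_range[1],
            inherits(fluid1, "fluid_spec"), inherits(fluid2, "fluid_spec"))
  if (water_fraction_mean <= 0 || water_fraction_mean >= 0.99)
    stop("water_fraction_mean must lie in (0, 0.99)")
  structure(list(n_cells = as.integer(n_cells),
                 dry_mass_median = dry_mass_median,
                 dry_mass_cv = dry_mass_cv,
                 dry_density_mean = dry_density_mean,
                 dry_density_cv = dry_density_cv,
                 water_fraction_mean = water_fraction_mean,
                 water_fraction_cv = water_fraction_cv,
                 fluid1 = fluid1, fluid2 = fluid2,
                 noise_scale = noise_scale,
                 exchange_time_constant = exchange_time_constant,
                 exposure_time_range = exposure_time_range,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0("<scenario_config> %d cells, dry mass ~ lognormal",
                     "(median %.4g fg, CV %.2g), dry density %.4g g/cm3 ",
                     "(CV %.2g),\n  water fraction %.2g (CV %.2g), fluids ",
                     "%s/%s, noise %.3g fg, exchange tau %.3g s, seed %d\n"),
              x$n_cells, x$dry_mass_median, x$dry_mass_cv,
              x$dry_density_mean, x$dry_density_cv, x$water_fraction_mean,
              x$water_fraction_cv, x$fluid1$label, x$fluid2$label,
              x$noise_scale, x$exchange_time_constant, x$seed))
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate a ground-truth cell population
#'
#' Draws per-cell dry masses (lognormal at the configured median and CV),
#' dry densities and water fractions (truncated normal), derives water
#' volumes so that the water fraction of total volume is exact per cell,
#' assigns exposure times, and records the noiseless buoyant masses in each
#' fluid under complete exchange. Deterministic given `config$seed`.
#'
#' @param config A [scenario_config].
#' @return Data frame of class `"truth_table"`: `cell_id`, `dry_mass` (fg),
#'   `dry_density` (g/cm3), `dry_volume` (fL), `water_volume` (fL),
#'   `water_mass` (fg), `water_fraction`, `total_mass` (fg),
#'   `exposure_time` (s), `mb1_true`, `mb2_true` (fg; full exchange).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    n <- config$n_cells
    sdlog <- sqrt(log1p(config$dry_mass_cv^2))
    dry_mass <- stats::rlnorm(n, meanlog = log(config$dry_mass_median),
                              sdlog = sdlog)
    dry_density <- rtrunc_norm(n, config$dry_density_mean,
                               config$dry_density_cv * config$dry_density_mean,
                               lo = 1.0, hi = 2.5)
    wf <- rtrunc_norm(n, config$water_fraction_mean,
                      config$water_fraction_cv * config$water_fraction_mean,
                      lo = 0.01, hi = 0.99)
    dry_volume <- dry_mass / dry_density
    water_volume <- wf / (1 - wf) * dry_volume
    exposure_time <- stats::runif(n, config$exposure_time_range[1],
                                  config$exposure_time_range[2])
    cells <- cell_spec(dry_mass, dry_density, water_volume,
                       water_density = rho_h2o())
    out <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n)),
                      dry_mass = dry_mass,
                      dry_density = dry_density,
                      dry_volume = dry_volume,
                      water_volume = water_volume,
                      water_mass = water_volume * rho_h2o(),
                      water_fraction = wf,
                      total_mass = dry_mass + water_volume * rho_h2o(),
                      exposure_time = exposure_time,
                      mb1_true = forward_buoyant_mass(cells, config$fluid1),
                      mb2_true = forward_buoyant_mass(cells, config$fluid2),
                      stringsAsFactors = FALSE)
    class(out) <- c("truth_table", "data.frame")
    out
  })
}

#' Simulate noisy paired buoyant-mass records
#'
#' Produces two measurement records per cell, one in each fluid, in the
#' measurement-table schema. The second-fluid record applies a residual
#' unexchanged-H2O fraction `exp(-exposure_time / tau)` (0 for all cells
#' when the exchange time constant is 0, i.e. instantaneous exchange), and
#' independent noise is added to every record.
#'
#' @param truth A [generate_population()] result.
#' @param config The matching [scenario_config].
#' @param error Optional `"error_model"` to resample noise from; by default
#'   noise is normal with SD `config$noise_scale`.
#' @param seed Seed for the noise draws; defaults to `config$seed + 1` so a
#'   scenario is fully reproducible from its config alone.
#' @return Data frame with columns `cell_id`, `fluid_label`,
#'   `buoyant_mass_fg`, `exposure_time_s` (two rows per cell).
#' @export
simulate_measurements <- function(truth, config, error = NULL,
                                  seed = config$seed + 1L) {
  stopifnot(inherits(truth, "truth_table"),
            inherits(config, "scenario_config"))
  n <- nrow(truth)
  tau <- config$exchange_time_constant
  residual <- if (tau == 0) rep(0, n) else exp(-truth$exposure_time / tau)
  cells <- cell_spec(truth$dry_mass, truth$dry_density, truth$water_volume,
                     water_density = rho_h2o())
  mb1 <- forward_buoyant_mass(cells, config$fluid1)
  mb2 <- forward_buoyant_mass(cells, config$fluid2,
                              residual_h2o_fraction = residual)
  noise <- with_seed(seed, {
    if (is.null(error)) stats::rnorm(2L * n, 0, config$noise_scale)
    else sample_errors(error, 2L * n)
  })
  out <- data.frame(
    cell_id = rep(truth$cell_id, 2L),
    fluid_label = rep(c(config$fluid1$label, config$fluid2$label),
                      each = n),
    buoyant_mass_fg = c(mb1 + noise[seq_len(n)], mb2 + noise[n + seq_len(n)]),
    exposure_time_s = rep(truth$exposure_time, 2L),
    stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, out$fluid_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate same-fluid repeat pairs for noise calibration
#'
#' Emulates the error-calibration protocol: each of `n_cells` cells is
#' weighed twice sequentially in the same fluid with independent noise, the
#' input [estimate_error_model()] expects. Defaults to 100 cells, the usual
#' protocol size.
#'
#' @param truth A [generate_population()] result.
#' @param config The matching [scenario_config] (provides fluid and noise
#'   scale).
#' @param n_cells Number of cells measured twice (capped at the population).
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return Data frame: `cell_id`, `m1`, `m2` (fg).
#' @export
generate_noise_calibration_pairs <- function(truth, config, n_cells = 100L,
                                             seed = config$seed + 2L) {
  stopifnot(inherits(truth, "truth_table"),
            inherits(config, "scenario_config"))
  n <- min(n_cells, nrow(truth))
  with_seed(seed, {
    idx <- sample(nrow(truth), n)
    mb <- truth$mb1_true[idx]
    data.frame(cell_id = truth$cell_id[idx],
               m1 = mb + stats::rnorm(n, 0, config$noise_scale),
               m2 = mb + stats::rnorm(n, 0, config$noise_scale),
               stringsAsFactors = FALSE)
  })
}

#' Named scenario presets
#'
#' Ready-made configurations emulating the benchmark populations: fixed
#' early-stationary E. coli (median dry mass 203 fg, water content ~516 fg),
#' exponential-phase E. coli (725 fg), and human erythrocytes (large dry
#' mass, very narrow dry-density distribution, high signal-to-noise).
#'
#' @param name Preset name; omit to get the full named list.
#' @return A [scenario_config], or a named list of them.
#' @export
scenario_presets <- function(name = NULL) {
  presets <- list(
    # 203 fg dry at 1.40 g/cm3 -> 145 fL dry volume; 516 fg water
    # (517 fL) -> water fraction 517/(517+145) = 0.781
    ecoli_stationary_fixed = scenario_config(
      n_cells = 500L, dry_mass_median = 203, dry_mass_cv = 0.35,
      dry_density_mean = 1.40, dry_density_cv = 0,
      water_fraction_mean = 0.781, noise_scale = 0.5, seed = 101L),
    ecoli_exponential = scenario_config(
      n_cells = 500L, dry_mass_median = 725, dry_mass_cv = 0.45,
      dry_density_mean = 1.41, dry_density_cv = 0,
      water_fraction_mean = 0.78, noise_scale = 0.5, seed = 102L),
    # ~30 pg dry content (mostly hemoglobin), narrow density spread,
    # 40-160x the bacterial signal at similar absolute noise
    erythrocyte = scenario_config(
      n_cells = 500L, dry_mass_median = 30000, dry_mass_cv = 0.12,
      dry_density_mean = 1.38, dry_density_cv = 0.002,
      water_fraction_mean = 0.70, noise_scale = 2, seed = 103L)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}
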