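# Systematic errors of the dry-density measurement.
#
# (1) Non-pure fluids: to keep cells iso-osmotic the measurements are made
# in PBS-based (not pure H2O / D2O) solutions, so the intracellular water is
# not exactly neutrally buoyant and the inversion -- which assumes it is --
# acquires a water-fraction-dependent bias.
# (2) Incomplete exchange: if intracellular H2O were not fully replaced by
# D2O by the time of the second weighing, dry-density estimates would drift
# with the time spent immersed in the D2O fluid; an exposure-time regression
# tests for this.

#' Systematic dry-density error from non-pure measurement fluids
#'
#' Forward-simulates a cell whose intracellular water keeps the pure-fluid
#' densities (H2O in the first fluid, the D2O mixture in the second) while
#' the immersion fluids themselves are denser (impermeable solutes such as
#' PBS salts added), then inverts with [solve_dry()] -- which wrongly assumes
#' the water term vanishes -- and returns estimated minus true dry density.
#'
#' @param true_cell A [cell_spec] (single cell) giving the true composition.
#' @param fluid1,fluid2 Permeable [fluid_spec]s whose `density` includes the
#'   solute departure and whose `intracellular_water_density` holds the
#'   pure-fluid water density.
#' @return Signed bias, g/cm3 (estimated - true).
#' @examples
#' f <- smr_fluids()
#' cell <- cell_spec(dry_mass = 140, dry_density = 1.4, water_volume = 400)
#' dry_density_bias(cell, f$h2o_pbs, f$d2o_pbs)
#' @export
dry_density_bias <- function(true_cell, fluid1, fluid2) {
  stopifnot(inherits(true_cell, "cell_spec"), nrow(true_cell) == 1L)
  check_fluid_pair(fluid1, fluid2)
  if (!fluid1$permeable || !fluid2$permeable)
    stop("dry_density_bias: both fluids must be permeable")
  c1 <- true_cell
  # water equilibrated with each fluid at the pure-fluid density
  cell1 <- cell_spec(c1$dry_mass, c1$dry_density, c1$water_volume,
                     water_density = fluid1$intracellular_water_density)
  cell2 <- cell_spec(c1$dry_mass, c1$dry_density, c1$water_volume,
                     water_density = fluid2$intracellular_water_density)
  mb1 <- forward_buoyant_mass(cell1, fluid1, residual_h2o_fraction = 1)
  mb2 <- forward_buoyant_mass(cell2, fluid2, residual_h2o_fraction = 1)
  est <- solve_dry(mb1, mb2, fluid1, fluid2)
  est$dry_density - c1$dry_density
}

#' Map the dry-density bias over water fraction and fluid departures
#'
#' Evaluates [dry_density_bias()] on a grid of intracellular water fractions
#' (of total cell volume) and density departures of each measurement fluid
#' from its pure base (pure H2O for the first fluid, the 9:1 D2O:H2O mixture
#' for the second). The zero-departure corner is exact (bias 0); along the
#' equal-departure diagonal the volume bias cancels and the bias reduces to
#' approximately \eqn{-\delta V_w/V_{dry}} at first order.
#'
#' @param water_fractions Water volume fractions in \[0, 0.99\].
#' @param departures1,departures2 Added fluid density (g/cm3) beyond the pure
#'   bases for the first and second fluid.
#' @param reference_cell_density True dry density of the probe cell, g/cm3.
#' @param pbs_point Departures `(d1, d2)` of the standard 1X PBS operating
#'   point, marked in the returned object. Defaults to 1.005 and 1.101 g/cm3
#'   fluids minus the pure bases.
#' @return Data frame of class `"bias_map"` with columns `water_fraction`,
#'   `departure1`, `departure2`, `bias` (g/cm3), and attributes `pbs_point`
#'   and `reference_cell_density`.
#' @export
bias_map <- function(water_fractions,
                     departures1 = seq(0, 0.02, by = 0.002),
                     departures2 = departures1,
                     reference_cell_density = 1.4,
                     pbs_point = c(1.005 - rho_h2o(),
                                   1.101 - d2o_mix_density())) {
  if (!length(water_fractions) || !length(departures1) || !length(departures2))
    stop("empty grid")
  if (any(water_fractions < 0 | water_fractions > 0.99))
    stop("water fractions must lie in [0, 0.99]")
  grid <- expand.grid(water_fraction = water_fractions,
                      departure1 = departures1,
                      departure2 = departures2,
                      KEEP.OUT.ATTRS = FALSE)
  rho_w1 <- rho_h2o()
  rho_w2 <- d2o_mix_density()
  grid$bias <- mapply(function(wf, d1, d2) {
    v_dry <- 100                      # fL; bias is scale-free in cell size
    v_w <- wf / (1 - wf) * v_dry
    cell <- cell_spec(v_dry * reference_cell_density,
                      reference_cell_density, v_w)
    f1 <- fluid_spec("f1", rho_w1 + d1, TRUE, rho_w1)
    f2 <- fluid_spec("f2", rho_w2 + d2, TRUE, rho_w2)
    dry_density_bias(cell, f1, f2)
  }, grid$water_fraction, grid$departure1, grid$departure2)
  structure(grid,
            pbs_point = pbs_point,
            reference_cell_density = reference_cell_density,
            class = c("bias_map", "data.frame"))
}

#' Exposure-time regression: a test for incomplete water exchange
#'
#' Ordinary least squares of per-cell dry density on the time spent immersed
#' in the second (D2O-based) fluid, with a one-sided t-test on the slope.
#' Under complete, rapid exchange the slope is zero; residual unexchanged
#' H2O depresses early-exposure density estimates (for cells denser than the
#' fluids), so incomplete exchange predicts a positive slope, the default
#' test direction. Significance is judged at a Bonferroni-corrected level
#' `0.05 / n_tests` when the regression is one of a batch of analyses.
#'
#' @param exposure_time Time in the second fluid, s.
#' @param dry_density Per-cell dry-density estimates, g/cm3.
#' @param n_tests Number of analyses in the batch for Bonferroni correction
#'   (default 1).
#' @param direction `"greater"` (default) tests slope > 0; `"less"` tests
#'   slope < 0.
#' @return Object of class `"exposure_regression"`: `slope` (g/cm3 per s),
#'   `p_value_one_sided`, `corrected_alpha`, `significant`, `r_squared`,
#'   `n`, `direction`, and the underlying `lm` fit.
#' @export
exposure_time_regression <- function(exposure_time, dry_density,
                                     n_tests = 1L,
                                     direction = c("greater", "less")) {
  direction <- match.arg(direction)
  ok <- is.finite(exposure_time) & is.finite(dry_density)
  exposure_time <- exposure_time[ok]; dry_density <- dry_density[ok]
  if (length(exposure_time) < 3L)
    stop("need at least 3 points for a slope test (p undefined at 2)")
  if (length(unique(exposure_time)) < 2L)
    stop("degenerate design: all exposure times equal")
  fit <- stats::lm(dry_density ~ exposure_time)
  sm <- summary(fit)
  tval <- sm$coefficients["exposure_time", "t value"]
  df <- fit$df.residual
  p <- if (direction == "greater") stats::pt(tval, df, lower.tail = FALSE)
       else stats::pt(tval, df, lower.tail = TRUE)
  alpha <- 0.05 / n_tests
  structure(list(slope = unname(stats::coef(fit)["exposure_time"]),
                 p_value_one_sided = unname(p),
                 corrected_alpha = alpha,
                 significant = unname(p < alpha),
                 r_squared = sm$r.squared,
                 n = length(exposure_time),
                 n_tests = n_tests,
                 direction = direction,
                 fit = fit),
            class = "exposure_regression")
}

#' @export
print.exposure_regression <- function(x, ...) {
  cat(sprintf(paste0("<exposure_regression> slope %.3g g/cm3 per s ",
                     "(n = %d, R2 = %.3f)\n  one-sided p (%s) = %.4g; ",
                     "alpha = %.4g (Bonferroni, %d tests): %s\n"),
              x$slope, x$n, x$r_squared, x$direction, x$p_value_one_sided,
              x$corrected_alpha, x$n_tests,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}
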