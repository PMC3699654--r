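# Closed-form inversions of paired buoyant-mass measurements.
# All masses in fg, volumes in fL, densities in g/cm3 (1 fg/fL = 1 g/cm3).

# Resolve the (mb1, mb2, fluids, cell_id, exposure_time) inputs shared by the
# solve_* functions: either two numeric vectors plus two fluid_specs, or a
# pair table from pair_measurements() carrying fluids as attributes.
resolve_pair_input <- function(mb1, mb2, fluid1, fluid2) {
  if (is.data.frame(mb1)) {
    pairs <- mb1
    req <- c("mb1", "mb2")
    miss <- setdiff(req, names(pairs))
    if (length(miss))
      stop("pair table lacks column(s): ", paste(miss, collapse = ", "))
    if (is.null(fluid1)) fluid1 <- attr(pairs, "fluid1")
    if (is.null(fluid2)) fluid2 <- attr(pairs, "fluid2")
    list(mb1 = pairs$mb1, mb2 = pairs$mb2,
         fluid1 = fluid1, fluid2 = fluid2,
         cell_id = pairs$cell_id, exposure_time = pairs$exposure_time)
  } else {
    list(mb1 = as.numeric(mb1), mb2 = as.numeric(mb2),
         fluid1 = fluid1, fluid2 = fluid2,
         cell_id = NULL, exposure_time = NULL)
  }
}

check_fluid_pair <- function(fluid1, fluid2) {
  stopifnot(inherits(fluid1, "fluid_spec"), inherits(fluid2, "fluid_spec"))
  if (fluid1$density == fluid2$density)
    stop("degenerate fluid pair: densities are equal (",
         fluid1$density, " g/cm3); the two-fluid inversion requires ",
         "fluids of differing density")
  invisible(TRUE)
}

# Shared two-fluid linear inversion: mass and volume from two buoyant masses.
two_fluid_invert <- function(mb1, mb2, rho1, rho2) {
  d <- rho2 - rho1
  list(mass = (mb1 * rho2 - mb2 * rho1) / d,
       volume = (mb1 - mb2) / d)
}

#' Dry mass, dry volume and dry density from a dual-fluid pair
#'
#' Inverts two buoyant-mass measurements of the same cell made in two
#' water-permeable fluids of differing density (an H2O-based and a D2O-based
#' solution). Under complete water exchange the intracellular water is
#' neutrally buoyant in each fluid and the pair isolates the dry content:
#' \deqn{m_{dry} = \frac{m_{b1}\rho_2 - m_{b2}\rho_1}{\rho_2 - \rho_1},
#'       \quad V_{dry} = \frac{m_{b1} - m_{b2}}{\rho_2 - \rho_1},
#'       \quad \rho_{dry} = m_{dry}/V_{dry}.}
#'
#' Measurement noise can push a small cell's inferred dry volume to zero or
#' below; such records are reported with `valid = FALSE` rather than dropped,
#' so downstream population filters are explicit.
#'
#' @param mb1,mb2 Buoyant masses (fg) in `fluid1` and `fluid2`, or a pair
#'   table from [pair_measurements()] as the first argument.
#' @param fluid1,fluid2 [fluid_spec] objects; taken from the pair table's
#'   attributes when omitted.
#' @return A data frame of class `"dry_result"` with columns `dry_mass` (fg),
#'   `dry_volume` (fL), `dry_density` (g/cm3) and `valid`; `cell_id` and
#'   `exposure_time` are carried through when present.
#' @examples
#' f <- smr_fluids()
#' solve_dry(57.275, 43.355, f$h2o_pbs, f$d2o_pbs)
#' @export
solve_dry <- function(mb1, mb2 = NULL, fluid1 = NULL, fluid2 = NULL) {
  inp <- resolve_pair_input(mb1, mb2, fluid1, fluid2)
  check_fluid_pair(inp$fluid1, inp$fluid2)
  if (!inp$fluid1$permeable || !inp$fluid2$permeable)
    stop("solve_dry requires two water-permeable fluids")
  if (any(!is.finite(inp$mb1)) || any(!is.finite(inp$mb2)))
    stop("buoyant masses must be finite")
  inv <- two_fluid_invert(inp$mb1, inp$mb2, inp$fluid1$density,
                          inp$fluid2$density)
  valid <- inv$volume > 0
  out <- data.frame(dry_mass = inv$mass,
                    dry_volume = inv$volume,
                    dry_density = ifelse(inv$volume != 0,
                                         inv$mass / inv$volume, NA_real_),
                    valid = valid)
  if (!is.null(inp$cell_id)) out <- cbind(cell_id = inp$cell_id, out)
  if (!is.null(inp$exposure_time)) out$exposure_time <- inp$exposure_time
  class(out) <- c("dry_result", "data.frame")
  out
}

#' Water mass and volume from a density-matched fluid pair
#'
#' The cell is weighed first in a dense impermeable fluid (e.g. OptiPrep in
#' H2O) and then in a D2O-based permeable fluid whose density has been
#' adjusted to match. The dry-material term is then identical in both
#' measurements and the difference is the buoyant mass of the intracellular
#' water in the impermeable fluid:
#' \eqn{m_{b1} - m_{b2} = V_w(\rho_w - \rho_f)}.
#'
#' @param mb1,mb2 Buoyant masses (fg) in the impermeable and the permeable
#'   fluid, or a pair table from [pair_measurements()].
#' @param fluid1 Impermeable [fluid_spec] (defines \eqn{\rho_f}).
#' @param fluid2 Permeable (D2O-based) [fluid_spec].
#' @param water_density Native density of the intracellular water (g/cm3).
#' @param density_tol Maximum allowed mismatch between the two fluid
#'   densities, g/cm3.
#' @return A data frame of class `"water_result"` with `water_mass` (fg) and
#'   `water_volume` (fL).
#' @export
solve_water <- function(mb1, mb2 = NULL, fluid1 = NULL, fluid2 = NULL,
                        water_density = rho_h2o(), density_tol = 0.001) {
  inp <- resolve_pair_input(mb1, mb2, fluid1, fluid2)
  fluid1 <- inp$fluid1; fluid2 <- inp$fluid2
  stopifnot(inherits(fluid1, "fluid_spec"), inherits(fluid2, "fluid_spec"))
  if (fluid1$permeable)
    stop("solve_water: fluid1 must be impermeable (water-retaining)")
  if (!fluid2$permeable)
    stop("solve_water: fluid2 must be water-permeable (D2O-based)")
  if (abs(fluid1$density - fluid2$density) > density_tol)
    stop(sprintf(paste0("matched-density violation: fluid densities differ ",
                        "by %.4f g/cm3 (tolerance %.4f)"),
                 abs(fluid1$density - fluid2$density), density_tol))
  rho_f <- fluid1$density
  if (rho_f == water_density)
    stop("degenerate: fluid density equals the water density; ",
         "the water term has no buoyant-mass signal")
  water_volume <- (inp$mb2 - inp$mb1) / (rho_f - water_density)
  out <- data.frame(water_mass = water_volume * water_density,
                    water_volume = water_volume)
  if (!is.null(inp$cell_id)) out <- cbind(cell_id = inp$cell_id, out)
  class(out) <- c("water_result", "data.frame")
  out
}

#' Total mass, volume and density from an impermeable fluid pair
#'
#' The classical two-fluid inversion: with no water exchange in either fluid
#' the whole cell behaves as a single particle, and two buoyant masses at two
#' fluid densities determine its total mass and volume.
#'
#' @inheritParams solve_dry
#' @return A data frame of class `"total_result"` with `total_mass` (fg),
#'   `total_volume` (fL), `total_density` (g/cm3) and `valid`.
#' @export
solve_total <- function(mb1, mb2 = NULL, fluid1 = NULL, fluid2 = NULL) {
  inp <- resolve_pair_input(mb1, mb2, fluid1, fluid2)
  check_fluid_pair(inp$fluid1, inp$fluid2)
  if (inp$fluid1$permeable || inp$fluid2$permeable)
    stop("solve_total requires two impermeable fluids (no water exchange)")
  inv <- two_fluid_invert(inp$mb1, inp$mb2, inp$fluid1$density,
                          inp$fluid2$density)
  valid <- inv$volume > 0
  out <- data.frame(total_mass = inv$mass,
                    total_volume = inv$volume,
                    total_density = ifelse(inv$volume != 0,
                                           inv$mass / inv$volume, NA_real_),
                    valid = valid)
  if (!is.null(inp$cell_id)) out <- cbind(cell_id = inp$cell_id, out)
  class(out) <- c("total_result", "data.frame")
  out
}

#' Dry fraction of a cell, by mass and by volume
#'
#' @param dry_mass,total_mass Masses in fg; percent by mass is
#'   `100 * dry_mass / total_mass`.
#' @param dry_volume,water_volume Volumes in fL; percent by volume is
#'   `100 * dry_volume / (dry_volume + water_volume)`. Both may be omitted to
#'   compute the mass fraction alone (and vice versa).
#' @return List with `percent_by_mass` and `percent_by_volume` (either may be
#'   `NA` when its inputs were not supplied).
#' @examples
#' percent_dry(dry_mass = 203, total_mass = 727,
#'             dry_volume = 145, water_volume = 580)
#' @export
percent_dry <- function(dry_mass = NULL, total_mass = NULL,
                        dry_volume = NULL, water_volume = NULL) {
  by_mass <- NA_real_
  by_volume <- NA_real_
  if (!is.null(dry_mass) && !is.null(total_mass)) {
    if (any(total_mass <= 0)) stop("total_mass must be positive")
    by_mass <- 100 * dry_mass / total_mass
  }
  if (!is.null(dry_volume) && !is.null(water_volume)) {
    tot <- dry_volume + water_volume
    if (any(tot <= 0)) stop("total volume must be positive")
    by_volume <- 100 * dry_volume / tot
  }
  list(percent_by_mass = by_mass, percent_by_volume = by_volume)
}
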