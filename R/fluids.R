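#' Immersion fluid specification
#'
#' A fluid in which cells are weighed on a suspended microchannel resonator
#' (SMR). Two properties matter for the inversion: the fluid's own density
#' (which sets the displaced-fluid term of buoyant mass) and the density the
#' cell's exchangeable water assumes once equilibrated with the fluid. For a
#' water-permeable heavy-water fluid the intracellular water exchanges to the
#' D2O mixture density; for an impermeable fluid (e.g. iodixanol/OptiPrep
#' solutions) the intracellular water keeps its native density.
#'
#' @param label Short identifier, e.g. `"H2O:PBS"`.
#' @param density Fluid density in g/cm3.
#' @param permeable Logical; can water cross the membrane and equilibrate
#'   with this fluid?
#' @param intracellular_water_density Density (g/cm3) the cell's exchangeable
#'   water assumes when fully equilibrated with this fluid. Ignored for
#'   impermeable fluids, where water keeps its native density; defaults to
#'   pure water for those.
#'
#' @return An object of class `"fluid_spec"`.
#' @examples
#' fluid_spec("H2O:PBS", density = 1.005, permeable = TRUE,
#'            intracellular_water_density = rho_h2o())
#' @export
fluid_spec <- function(label, density, permeable = TRUE,
                       intracellular_water_density = rho_h2o()) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(density) || density <= 0)
    stop("fluid density must be a positive finite number (g/cm3)")
  if (!is.finite(intracellular_water_density) ||
      intracellular_water_density <= 0)
    stop("intracellular_water_density must be positive and finite (g/cm3)")
  structure(
    list(label = label,
         density = as.numeric(density),
         permeable = isTRUE(permeable),
         intracellular_water_density = as.numeric(intracellular_water_density)),
    class = "fluid_spec")
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat(sprintf("<fluid_spec> %s: density %.4f g/cm3, %s, water -> %.4f g/cm3\n",
              x$label, x$density,
              if (x$permeable) "permeable" else "impermeable",
              x$intracellular_water_density))
  invisible(x)
}

#' Reference water densities
#'
#' Densities of pure H2O and pure D2O at the 22-23 C operating temperature,
#' and the density of a D2O:H2O volume mixture under ideal volume mixing.
#' These are the densities the intracellular water assumes in the two
#' measurement fluids when exchange is complete.
#'
#' @param d2o_fraction Volume fraction of D2O in the mixture (default 0.9,
#'   i.e. the 9:1 v/v D2O:H2O working fluid).
#' @return Density in g/cm3.
#' @export
rho_h2o <- function() 0.9975

#' @rdname rho_h2o
#' @export
rho_d2o <- function() 1.1040

#' @rdname rho_h2o
#' @export
d2o_mix_density <- function(d2o_fraction = 0.9) {
  stopifnot(d2o_fraction >= 0, d2o_fraction <= 1)
  d2o_fraction * rho_d2o() + (1 - d2o_fraction) * rho_h2o()
}

#' Standard SMR measurement fluids
#'
#' The default fluid set used throughout: 1X PBS in H2O (1.005 g/cm3),
#' 1X PBS in 9:1 D2O:H2O (1.101 g/cm3), and an OptiPrep:PBS:H2O solution
#' density-matched to the D2O fluid for water-content measurements.
#'
#' By default the equilibrated intracellular water densities are the
#' pure-fluid values (pure H2O and the 9:1 mixture), so the PBS salts make
#' the water slightly non-neutrally buoyant — the source of the systematic
#' bias quantified by [dry_density_bias()]. With `water_neutral = TRUE` the
#' equilibrated water density is set equal to each permeable fluid's own
#' density, the idealization under which the two-fluid inversion is exact;
#' this is the operating assumption of the analysis and the default
#' condition emulated by the synthetic-data generator.
#'
#' @param water_neutral If `TRUE`, exchanged intracellular water is exactly
#'   neutrally buoyant in the permeable fluids.
#' @return Named list of [fluid_spec] objects
#'   (`h2o_pbs`, `d2o_pbs`, `optiprep_pbs`).
#' @export
smr_fluids <- function(water_neutral = FALSE) {
  icw1 <- if (water_neutral) 1.005 else rho_h2o()
  icw2 <- if (water_neutral) 1.101 else d2o_mix_density()
  list(
    h2o_pbs = fluid_spec("H2O:PBS", density = 1.005, permeable = TRUE,
                         intracellular_water_density = icw1),
    d2o_pbs = fluid_spec("D2O:PBS", density = 1.101, permeable = TRUE,
                         intracellular_water_density = icw2),
    optiprep_pbs = fluid_spec("OptiPrep:PBS", density = 1.101,
                              permeable = FALSE,
                              intracellular_water_density = rho_h2o())
  )
}

#' Ground-truth cell composition
#'
#' Describes one or more cells for the forward model: the mass and density of
#' the non-aqueous (dry) material and the volume and native density of the
#' exchangeable water. Vectorized: supply equal-length vectors to describe a
#' population.
#'
#' @param dry_mass Dry mass in fg (>= 0).
#' @param dry_density Dry density in g/cm3 (> 0).
#' @param water_volume Exchangeable water volume in fL (>= 0).
#' @param water_density Native density of the intracellular water in g/cm3;
#'   defaults to pure H2O.
#' @return A data frame of class `"cell_spec"` with the supplied columns plus
#'   the derived `dry_volume` (fL). Units: 1 fg/fL = 1 g/cm3.
#' @export
cell_spec <- function(dry_mass, dry_density, water_volume = 0,
                      water_density = rho_h2o()) {
  n <- max(length(dry_mass), length(dry_density), length(water_volume),
           length(water_density))
  dry_mass <- rep_len(as.numeric(dry_mass), n)
  dry_density <- rep_len(as.numeric(dry_density), n)
  water_volume <- rep_len(as.numeric(water_volume), n)
  water_density <- rep_len(as.numeric(water_density), n)
  if (any(!is.finite(dry_mass)) || any(dry_mass < 0))
    stop("dry_mass must be finite and >= 0 (fg)")
  if (any(!is.finite(dry_density)) || any(dry_density <= 0))
    stop("dry_density must be finite and > 0 (g/cm3)")
  if (any(!is.finite(water_volume)) || any(water_volume < 0))
    stop("water_volume must be finite and >= 0 (fL)")
  if (any(!is.finite(water_density)) || any(water_density <= 0))
    stop("water_density must be finite and > 0 (g/cm3)")
  structure(
    data.frame(dry_mass = dry_mass,
               dry_density = dry_density,
               dry_volume = dry_mass / dry_density,
               water_volume = water_volume,
               water_density = water_density),
    class = c("cell_spec", "data.frame"))
}

#' Forward model: buoyant mass of a cell in a fluid
#'
#' Buoyant mass decomposes into the dry-material term and the intracellular
#' water term:
#' \deqn{m_b = m_{dry}(1 - \rho_f/\rho_{dry}) + V_w(\rho_{w,eff} - \rho_f)}
#' where the effective water density interpolates linearly between the
#' native water density (no exchange) and the fluid's equilibrated
#' intracellular water density (complete exchange) according to the residual
#' H2O fraction. Impermeable fluids force the residual fraction to 1 (no
#' exchange can occur).
#'
#' @param cell A [cell_spec] (one or more cells).
#' @param fluid A [fluid_spec].
#' @param residual_h2o_fraction Fraction of the native water not yet
#'   exchanged, in \[0, 1\]: 1 = no exchange, 0 = complete exchange.
#'   Recycled across cells. Default 0 for permeable fluids (the analysis
#'   assumption of rapid, complete exchange).
#' @return Buoyant mass(es) in fg. May be negative: cells float in a dense
#'   impermeable fluid.
#' @examples
#' f <- smr_fluids()
#' cell <- cell_spec(dry_mass = 203, dry_density = 1.40, water_volume = 517)
#' forward_buoyant_mass(cell, f$h2o_pbs)
#' forward_buoyant_mass(cell, f$d2o_pbs)
#' @export
forward_buoyant_mass <- function(cell, fluid, residual_h2o_fraction = 0) {
  stopifnot(inherits(cell, "cell_spec"), inherits(fluid, "fluid_spec"))
  r <- as.numeric(residual_h2o_fraction)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("residual_h2o_fraction must lie in [0, 1]")
  if (!fluid$permeable) r <- 1
  rho_f <- fluid$density
  rho_w_eff <- r * cell$water_density +
    (1 - r) * fluid$intracellular_water_density
  cell$dry_mass * (1 - rho_f / cell$dry_density) +
    cell$water_volume * (rho_w_eff - rho_f)
}
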