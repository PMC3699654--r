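# Shared fixtures: fluid pairs and small populations built in code.

pbs_fluids <- function() smr_fluids()

# Pure-fluid pair: each fluid's equilibrated intracellular water density
# equals its own density, so fully exchanged water is exactly neutrally
# buoyant and solve_dry is exact.
pure_fluids <- function() {
  list(
    h2o = fluid_spec("pure_H2O", rho_h2o(), TRUE, rho_h2o()),
    d2o = fluid_spec("pure_D2O_mix", d2o_mix_density(), TRUE,
                     d2o_mix_density())
  )
}

# Impermeable pair for total-content inversions.
impermeable_fluids <- function() {
  list(
    lo = fluid_spec("percoll_lo", 1.005, FALSE),
    hi = fluid_spec("percoll_hi", 1.101, FALSE)
  )
}

random_cells <- function(n, seed) {
  set.seed(seed)
  cell_spec(dry_mass = runif(n, 50, 2000),
            dry_density = runif(n, 1.2, 1.6),
            water_volume = runif(n, 0, 5000))
}
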