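# drycell

Single-cell dry mass, dry density and water content from dual-fluid
buoyant-mass measurements.

## The measurement

A suspended microchannel resonator (SMR) weighs one cell at a time as it
transits a vibrating microfluidic cantilever, reporting the cell's *buoyant
mass*

```
m_b = m − V·ρ_f = V·(ρ − ρ_f),
```

its mass minus the mass of fluid it displaces. One reading cannot separate
mass from volume, but two sequential readings in fluids of different density
can. `drycell` implements the dual-fluid variant in which the cell is weighed
first in a water-based solution and then in a heavy-water (D₂O) based one:
intracellular H₂O exchanges for D₂O within seconds, so in each fluid the
cell's water is (to good approximation) neutrally buoyant and the pair of
measurements isolates the **dry content** alone. Decomposing

```
m_b = m_dry·(1 − ρ_f/ρ_dry) + V_w·(ρ_w − ρ_f)
```

and dropping the vanishing water term in both fluids gives closed forms for
dry mass, dry volume and their ratio, the **dry density** — the
abundance-weighted mean density of the cell's biomolecules, a label-free
readout of bulk biochemical composition (RNA is denser than protein is
denser than lipid):

```
m_dry = (m_b1·ρ2 − m_b2·ρ1)/(ρ2 − ρ1),   V_dry = (m_b1 − m_b2)/(ρ2 − ρ1).
```

Weighing instead in a dense *impermeable* fluid (iodixanol/OptiPrep) matched
in density to the D₂O fluid yields the cell's water mass and volume from the
difference of the two readings, and a pair of impermeable fluids recovers
total mass, volume and density.

The package is aimed at SMR users and at anyone studying single-cell
biophysical composition: it provides the forward model and inversions, the
measurement-noise machinery needed to interpret dry-density spread
(the small density difference between the two fluids amplifies
single-measurement error ~15× in dry mass, and non-linearly in dry
density), systematic-bias maps for isotonic (non-pure) fluids, exposure-time
regressions that test the complete-exchange assumption, population
statistics, and a synthetic-data generator so every stage is testable
without instrument data.

## Worked example

Simulate a fixed early-stationary *E. coli*-like experiment, estimate the
measurement error from repeat pairs, invert to dry composition, and compare
the observed dry-density spread to the noise-only expectation:

```r
library(drycell)

cfg     <- scenario_presets("ecoli_stationary_fixed")   # median 203 fg, ρ_dry 1.40
truth   <- generate_population(cfg)
records <- simulate_measurements(truth, cfg)            # 2 noisy readings/cell
pairs   <- pair_measurements(records, cfg$fluid1, cfg$fluid2)

dry <- solve_dry(pairs)
head(dry, 3)
#>      cell_id dry_mass dry_volume dry_density valid exposure_time
#> 1 cell_00001 183.6965   131.6816    1.395005  TRUE      3.947066
#> 2 cell_00002 250.8638   180.4613    1.390125  TRUE     18.465298
#> 3 cell_00003 152.8315   107.4384    1.422503  TRUE      8.355628

em <- estimate_error_model(
  generate_noise_calibration_pairs(truth, cfg)[, c("m1", "m2")])
em
#> <error_model> scale 0.4809 fg from 100 samples (mean 0.0596 fg)

ms <- median_summary(dry$dry_mass[dry$valid], seed = 1)
sprintf("median dry mass: %.1f +/- %.1f fg (n = %d)", ms$median, ms$se, ms$n)
#> "median dry mass: 198.0 +/- 4.0 fg (n = 500)"

null <- simulate_null_density(dry$dry_mass[dry$valid],
                              median(dry$dry_density[dry$valid]),
                              cfg$fluid1, cfg$fluid2, em,
                              n_sim = 10000, seed = 2)
null
#> <null_density> 10000 simulated cells at median density 1.4012 g/cm3
#>   99% bounds: [1.3536, 1.4805] g/cm3

compare_to_null(dry$dry_density[dry$valid], null)$fraction_outside
#> [1] 0.01
```

Reading: the bootstrap median dry mass (198 ± 4 fg) recovers the configured
203 fg; the single-measurement error (~0.48 fg) estimated from 100 repeat
pairs recovers the simulated 0.5 fg; and the observed dry-density spread sits
entirely inside the noise-only 99% bounds (exceedance 0.01, exactly the
nominal rate), i.e. this population shows no resolvable biological
dry-density heterogeneity at this noise level — the correct answer, since the
generator drew every cell at ρ_dry = 1.40. The error-amplification factor for
this fluid pair is `dry_mass_error_factor(1.005, 1.101)` = 15.53.

Other entry points: `solve_water()` / `solve_total()` for water and total
content, `dry_density_bias()` / `bias_map()` for the isotonic-fluid
systematic error, `exposure_time_regression()` for incomplete-exchange
testing, `rescaled_kde()`, `mann_whitney_u()`, `deming_fit()`,
`logistic_growth_fit()` and `batch_summary()` for the population-level
analyses, and `read_measurements()` / `read_fluids()` /
`pair_measurements()` / `write_results()` for CSV I/O. See the methods
vignette (`vignettes/dual-fluid-dry-mass.Rmd`) for the model, assumptions
and parameter choices.

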