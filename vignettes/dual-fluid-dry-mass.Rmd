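---
title: "Dual-fluid buoyant-mass analysis: model, noise and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-fluid buoyant-mass analysis: model, noise and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drycell)
```

## The physical model

A suspended microchannel resonator weighs a particle immersed in a fluid of
density $\rho_f$ as its buoyant mass $m_b = m - V\rho_f$. `drycell` works
with the two-component decomposition of a cell into dry material and
exchangeable water,

$$m_b \;=\; m_{dry}\!\left(1 - \frac{\rho_f}{\rho_{dry}}\right)
        \;+\; V_w\,(\rho_{w,\mathrm{eff}} - \rho_f),$$

implemented by `forward_buoyant_mass()`. The effective water density
interpolates linearly between the native water density (no exchange) and
the density the water assumes once equilibrated with the fluid (complete
exchange), controlled by a residual-H₂O fraction in $[0,1]$; impermeable
fluids force that fraction to 1. All quantities are carried in fg, fL and
g·cm⁻³, which are mutually consistent (1 fg/fL = 1 g·cm⁻³).

Three inversions follow, each a closed form over a pair of measurements:

* **Dry content** (`solve_dry()`): two *permeable* fluids of different
  density, water assumed fully exchanged and neutrally buoyant in each.
  The inversion is linear in $(m_{b1}, m_{b2})$; dry density depends only
  on their ratio (the angle in the $(m_{b1}, m_{b2})$ plane), which is why
  it is exactly invariant under common rescaling of both measurements —
  a property the tests exercise directly.
* **Water content** (`solve_water()`): an impermeable dense fluid and a
  permeable D₂O-based fluid *matched in density*; the dry term cancels in
  the difference and $m_{b1}-m_{b2} = V_w(\rho_w-\rho_f)$.
* **Total content** (`solve_total()`): two impermeable fluids; the
  classical whole-particle two-fluid inversion.

### Assumptions, and where they are relaxed

The dry inversion rests on two assumptions, each of which the package can
interrogate rather than take on faith:

1. **Exchanged water is neutrally buoyant.** Measurements are made in
   isotonic (PBS-based) solutions, not pure H₂O/D₂O, so the intracellular
   water is slightly denser than neutral. `dry_density_bias()` quantifies
   the resulting systematic error exactly by running the forward model with
   the water term retained and inverting with the neutral-buoyancy
   assumption; `bias_map()` grids it over water fraction and per-fluid
   density departures. For equal departures $\delta$ in both fluids the
   inferred dry volume is exact and the bias reduces to
   $-\delta\,V_w/V_{dry}$ at first order (the map agrees with this closed
   form to $10^{-6}$ for $\delta \le 0.01$). For a cell 80% water by
   volume at the 1X PBS operating point the magnitude is ~0.03 g·cm⁻³,
   under the 0.04 g·cm⁻³ bound that makes the method usable without a
   water-fraction correction.
2. **Exchange is complete within seconds.** `exposure_time_regression()`
   regresses per-cell dry density on the time spent in the D₂O fluid
   (ordinary least squares via `stats::lm`) with a one-sided t-test on the
   slope at a Bonferroni-corrected level $0.05/n_{tests}$. Residual H₂O
   makes early-exposure estimates too low for cells denser than the
   fluids, so the predicted alternative is a *positive* slope — the
   default test direction (the choice is configurable; only the one-sided
   character is inherent, the direction follows from the physics).

## Measurement noise

Single-measurement error is estimated empirically (`estimate_error_model()`)
from sequential repeat weighings of the same cells in the same fluid: each
difference is a difference of two independent errors, so dividing the
differences by $\sqrt2$ yields the single-measurement error distribution
and its standard deviation. Around 100 pairs — the usual protocol — gives a
serviceable scale; the estimator is consistent as pairs accumulate.

Because the two fluids differ by only ~0.1 g·cm⁻³, the linear dry-mass
inversion amplifies this error by
$\sqrt{\rho_1^2+\rho_2^2}/|\rho_2-\rho_1|$ (`dry_mass_error_factor()`),
about 15.5-fold for the 1.005/1.101 pair; `mc_dry_mass_error_factor()`
confirms the closed form by direct simulation. Dry *density* is a ratio of
linear forms, so its error is propagated by Monte Carlo rather than
analytically: `simulate_null_density()` resamples observed dry masses with
replacement, computes both noiseless buoyant masses at a single reference
density, perturbs each with independent errors resampled from the empirical
error distribution, and re-inverts. The empirical 0.5% and 99.5% quantiles
of the resulting densities are the "99% bounds": the spread expected if
every cell truly had the reference density. `compare_to_null()` reports the
exceedance fraction and a Q–Q table; deliberately no hypothesis-test
verdict is attached, since the question ("is the observed heterogeneity
more than noise?") is answered by the comparison itself.

Two modeling alternatives are provided behind flags because the choice is
not forced by anything observable at these sample sizes: masses can be
resampled plainly (default) or with a normal-kernel smear at the Silverman
bandwidth (`smooth_masses = TRUE`), and errors can be resampled empirically
(default) or drawn from a fitted normal (`parametric_errors = TRUE`).

## The synthetic-data generator

`scenario_config()` + `generate_population()` + `simulate_measurements()`
emulate a dual-fluid experiment end to end: lognormal dry masses (positive
and right-skewed, as real dry-mass distributions are) specified by median
and CV; truncated-normal dry densities and water fractions; exposure times
uniform on 1–30 s (the two weighings are made several seconds apart);
independent normal noise at a configurable scale on every record; and an
optional exponential exchange time constant $\tau$, under which the second
reading carries a residual-H₂O fraction $e^{-t/\tau}$ ($\tau = 0$ means
instantaneous, complete exchange). Every stochastic operation takes or
derives a seed and is reproducible byte for byte; `run_manifest()` snapshots
config, seeds and file digests.

The default fluid pair is the PBS pair under the **neutral-water
idealization** (`smr_fluids(water_neutral = TRUE)`): exchange renders the
intracellular water exactly neutrally buoyant, which is the regime the
inversion assumes and therefore the right null condition for testing
recovery of known parameters. Passing fluids with pure-fluid water
densities (`smr_fluids()`) instead makes the generator reproduce the
isotonic-fluid systematic bias — deliberately, as input for the bias
module, not as a default confound in every simulation.

Presets (`scenario_presets()`) encode three benchmark populations: fixed
early-stationary *E. coli* (median dry mass 203 fg, dry density 1.40
g·cm⁻³, water fraction 0.781 — chosen so the implied water content is
~516 fg, i.e. 517 fL against a 145 fL dry volume), exponential-phase
*E. coli* (725 fg), and human erythrocytes (30 pg dry content, mostly
hemoglobin, with a very narrow density spread and ~40–160× the bacterial
signal at similar absolute noise). Dry-mass CVs (0.35, 0.45, 0.12) and the
erythrocyte density CV (0.002) are population-shape choices consistent
with the breadth of the corresponding published distributions; bacterial
presets set the dry-density CV to 0 because at bacterial signal-to-noise
the observable spread is dominated by measurement error, making the
homogeneous population the informative default. The single-measurement
noise scale defaults to 0.5 fg for the bacterial presets and 2 fg for
erythrocytes.

What the generator does **not** emulate: osmotic volume changes between
fluids, deuterium incorporation into dry matter, flow-path-dependent
sensitivity, the fluid-switch transient, or cell-cycle structure. Passing
tests therefore demonstrate correctness of the inversion and inference
machinery under the model's own assumptions — not robustness to every
artifact of real instruments.

## Population statistics

* `rescaled_kde()`: Gaussian KDE via `stats::density`, divided by its
  maximum so distributions of different n overlay; Scott's bandwidth rule
  by default (Silverman available), recorded in the output along with the
  pre-rescale peak so the raw density is recoverable.
* `median_summary()` / `batch_summary()`: medians with bootstrap standard
  errors (1000 seeded resamples by default). A "±" on a median in this
  package always means that bootstrap SE.
* `mann_whitney_u()`: exact permutation enumeration of U for groups of up
  to 8 each (tie-safe), tie-corrected continuity-corrected normal
  approximation above; two-sided by symmetric distance from the null mean.
* `deming_fit()`: closed-form total least squares with an error-variance
  ratio $\delta$ (1 = orthogonal regression, the default — the natural
  reading of an instrument-comparison fit when neither error variance is
  published).
* `logistic_growth_fit()`: `stats::nls` on $K/(1+e^{-r(t-t_0)})$ with
  data-driven starts (K from the max, $t_0$ from the half-max crossing,
  $r$ from the logit-slope of the rising phase), a zero-residual-safe
  convergence offset, and a tight polish refit; non-convergence is an
  error carrying the starting values, a decreasing series a warning.

## Numerical choices and degenerate inputs

* Water-density constants: $\rho(\mathrm{H_2O}) = 0.9975$,
  $\rho(\mathrm{D_2O}) = 1.1040$ g·cm⁻³ at 22–23 °C, 9:1 v/v mixture by
  ideal volume mixing (1.09335 g·cm⁻³); all overridable per fluid.
* Matched-density tolerance for the water inversion: 0.001 g·cm⁻³ by
  default (the experimental matching is manual, to the instrument's
  density resolution), configurable.
* Equal fluid densities, impermeable fluids handed to `solve_dry()`,
  all-equal calibration abscissae, sub-2-point fits and empty groups are
  errors with named causes; a non-positive inferred dry volume is *not* an
  error — the record is reported with `valid = FALSE` so that population
  filtering is explicit and countable, since silently dropping
  noise-straddling small cells would bias medians.
* Null-distribution floor: `n_sim` ≥ 10000 is the intended regime (a
  warning below); quantile noise on the 99% bounds at $10^4$ draws is
  ±0.5% coverage, the tolerance the tests assert.

## Problem sizes

The shipped tests and examples run populations of 300–500 cells, error
models from 100–1000 repeat pairs, null distributions of $10^4$ draws and
bootstraps of 1000 resamples — sizes at which every asserted tolerance
(2% Monte-Carlo agreement, 0.5% coverage, 10% scale recovery) has
comfortable sampling margin while the full suite completes in seconds.
Larger simulations only sharpen the same comparisons.
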