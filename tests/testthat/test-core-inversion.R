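# Forward buoyant-mass model and the dry/water/total closed-form inversions.

test_that("forward buoyant mass matches hand-checked arithmetic", {
  f <- pbs_fluids()
  dry_only <- cell_spec(dry_mass = 203, dry_density = 1.40, water_volume = 0)
  # 203 * (1 - 1.005/1.40) and 203 * (1 - 1.101/1.40)
  expect_equal(forward_buoyant_mass(dry_only, f$h2o_pbs), 57.275)
  expect_equal(forward_buoyant_mass(dry_only, f$d2o_pbs), 43.355)
  # neutral buoyancy: dry density equal to fluid density, no water signal
  neutral <- cell_spec(dry_mass = 100, dry_density = 1.005, water_volume = 0)
  expect_equal(forward_buoyant_mass(neutral, f$h2o_pbs), 0)
  expect_error(forward_buoyant_mass(dry_only, f$h2o_pbs,
                                    residual_h2o_fraction = 1.5),
               "\\[0, 1\\]")
})

test_that("residual-H2O interpolation and impermeable override behave", {
  f <- pbs_fluids()
  cell <- cell_spec(200, 1.4, water_volume = 500,
                    water_density = rho_h2o())
  full <- forward_buoyant_mass(cell, f$d2o_pbs, residual_h2o_fraction = 0)
  none <- forward_buoyant_mass(cell, f$d2o_pbs, residual_h2o_fraction = 1)
  half <- forward_buoyant_mass(cell, f$d2o_pbs, residual_h2o_fraction = 0.5)
  expect_equal(half, (full + none) / 2)
  # impermeable fluid forces no exchange regardless of the requested fraction
  opti <- f$optiprep_pbs
  expect_equal(forward_buoyant_mass(cell, opti, residual_h2o_fraction = 0),
               forward_buoyant_mass(cell, opti, residual_h2o_fraction = 1))
})

test_that("buoyant mass decreases in fluid density with slope -(Vdry + Vw)", {
  cell <- cell_spec(300, 1.45, water_volume = 800)
  rho <- c(1.00, 1.05, 1.10)
  mb <- vapply(rho, function(r)
    forward_buoyant_mass(cell, fluid_spec("x", r, TRUE, 0.9975),
                         residual_h2o_fraction = 1), numeric(1))
  slopes <- diff(mb) / diff(rho)
  expect_equal(slopes, rep(-(cell$dry_volume + cell$water_volume), 2))
})

test_that("solve_dry recovers the worked dual-fluid example", {
  f <- pbs_fluids()
  res <- solve_dry(57.275, 43.355, f$h2o_pbs, f$d2o_pbs)
  expect_equal(res$dry_mass, 203)
  expect_equal(res$dry_volume, 145)
  expect_equal(res$dry_density, 1.400)
  expect_true(res$valid)
})

test_that("forward -> solve_dry round trip is exact for random cells", {
  pf <- pure_fluids()
  cells <- random_cells(50, seed = 42)
  mb1 <- forward_buoyant_mass(cells, pf$h2o)
  mb2 <- forward_buoyant_mass(cells, pf$d2o)
  res <- solve_dry(mb1, mb2, pf$h2o, pf$d2o)
  expect_equal(res$dry_mass, cells$dry_mass, tolerance = 1e-9)
  expect_equal(res$dry_volume, cells$dry_volume, tolerance = 1e-9)
  expect_equal(res$dry_density, cells$dry_density, tolerance = 1e-9)
})

test_that("solve_dry degenerate inputs are flagged, not dropped", {
  f <- pbs_fluids()
  res <- solve_dry(10, 10, f$h2o_pbs, f$d2o_pbs)
  expect_equal(res$dry_volume, 0)
  expect_false(res$valid)
  expect_true(is.na(res$dry_density))
  same <- fluid_spec("same", 1.005, TRUE)
  expect_error(solve_dry(10, 5, f$h2o_pbs, same), "degenerate fluid pair")
  imp <- fluid_spec("percoll_lo", 1.005, permeable = FALSE)
  expect_error(solve_dry(10, 5, imp, f$d2o_pbs), "permeable")
})

test_that("dry density depends only on the buoyant-mass ratio (angle
           in the (mb1, mb2) plane)", {
  f <- pbs_fluids()
  base <- solve_dry(57.275, 43.355, f$h2o_pbs, f$d2o_pbs)
  for (c_scale in c(0.1, 0.5, 2, 17.3)) {
    scaled <- solve_dry(c_scale * 57.275, c_scale * 43.355,
                        f$h2o_pbs, f$d2o_pbs)
    expect_equal(scaled$dry_density, base$dry_density)
    expect_equal(scaled$dry_mass, c_scale * base$dry_mass)
  }
})

test_that("solve_dry is independent of water volume under full exchange in
           pure fluids", {
  pf <- pure_fluids()
  v_dry <- 145
  for (v_w in c(0, 10, 145, 500, 1450)) {
    cell <- cell_spec(203, 1.4, water_volume = v_w)
    res <- solve_dry(forward_buoyant_mass(cell, pf$h2o),
                     forward_buoyant_mass(cell, pf$d2o), pf$h2o, pf$d2o)
    expect_equal(res$dry_mass, 203, tolerance = 1e-12)
    expect_equal(res$dry_volume, v_dry, tolerance = 1e-9)
  }
})

test_that("two-part decomposition equals whole-cell buoyant mass", {
  cells <- random_cells(20, seed = 7)
  for (rho_f in c(1.005, 1.101)) {
    fl <- fluid_spec("x", rho_f, TRUE, 1.05)
    for (r in c(0, 0.3, 1)) {
      mb <- forward_buoyant_mass(cells, fl, residual_h2o_fraction = r)
      rho_w_eff <- r * cells$water_density + (1 - r) * 1.05
      whole_mass <- cells$dry_mass + cells$water_volume * rho_w_eff
      whole_vol <- cells$dry_volume + cells$water_volume
      expect_equal(mb, whole_mass - whole_vol * rho_f)
    }
  }
})

test_that("solve_water recovers the water content from matched fluids", {
  f <- pbs_fluids()
  # forward model with V_w = 517 fL, rho_w = 0.998: mb1 - mb2 = -53.251 fg
  res <- solve_water(10, 10 + 53.251, f$optiprep_pbs, f$d2o_pbs,
                     water_density = 0.998)
  expect_equal(res$water_volume, 517.0)
  expect_equal(res$water_mass, 515.966)
  # no differential signal -> no water
  zero <- solve_water(10, 10, f$optiprep_pbs, f$d2o_pbs)
  expect_equal(zero$water_mass, 0)
})

test_that("solve_water enforces its preconditions", {
  f <- pbs_fluids()
  off <- fluid_spec("off_density_D2O", 1.111, TRUE, d2o_mix_density())
  expect_error(solve_water(10, 20, f$optiprep_pbs, off),
               "matched-density violation")
  expect_error(solve_water(10, 20, f$h2o_pbs, f$d2o_pbs), "impermeable")
  deg_f1 <- fluid_spec("neutral", 0.998, FALSE)
  deg_f2 <- fluid_spec("neutral2", 0.998, TRUE)
  expect_error(solve_water(10, 20, deg_f1, deg_f2, water_density = 0.998),
               "degenerate")
})

test_that("solve_total inverts whole-particle mass, volume and density", {
  imp <- impermeable_fluids()
  # cell: total mass 727 fg, total volume 626.72 fL (density ~1.16)
  m <- 727; v <- 626.72
  mb1 <- m - v * 1.005
  mb2 <- m - v * 1.101
  res <- solve_total(mb1, mb2, imp$lo, imp$hi)
  expect_equal(res$total_mass, 727)
  expect_equal(res$total_volume, 626.72)
  expect_equal(res$total_density, 727 / 626.72)
  # scaling both measurements scales mass/volume, not density
  sc <- solve_total(3 * mb1, 3 * mb2, imp$lo, imp$hi)
  expect_equal(sc$total_mass, 3 * res$total_mass)
  expect_equal(sc$total_density, res$total_density)
  expect_false(solve_total(5, 5, imp$lo, imp$hi)$valid)
  expect_error(solve_total(mb1, mb2, pbs_fluids()$h2o_pbs, imp$hi),
               "impermeable")
})

test_that("percent_dry computes mass and volume fractions", {
  pd <- percent_dry(dry_mass = 203, total_mass = 727,
                    dry_volume = 145, water_volume = 580)
  expect_equal(round(pd$percent_by_mass), 28)
  expect_equal(pd$percent_by_volume, 20)
  expect_equal(percent_dry(5, 5)$percent_by_mass, 100)
  expect_error(percent_dry(1, 0), "positive")
})
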