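test_that("seawater density reproduces the published one-atmosphere check values", {
  expect_equal(sw_density(0, 5), 999.96675, tolerance = 1e-7)
  expect_equal(sw_density(35, 5), 1027.67547, tolerance = 1e-7)
  expect_equal(sw_density(35, 25), 1023.34306, tolerance = 1e-7)
})

test_that("N^2 is zero for uniform water and g*drho/(rho0*dz) for two layers", {
  bf <- buoyancy_frequency(c(10, 20, 30, 40), rep(12, 4), rep(35, 4))
  expect_equal(bf$n2, rep(0, 4), tolerance = 1e-10)

  # two layers differing by ~1 kg m^-3 across 10 m
  t_top <- 17.0
  # find the temperature giving exactly +1 kg/m3 at S = 35
  f <- function(t) sw_density(35, t) - sw_density(35, t_top) - 1
  t_bot <- uniroot(f, c(10, 17), tol = 1e-12)$root
  bf2 <- buoyancy_frequency(c(5, 15), c(t_top, t_bot), 35, rho0 = 1025,
                            g = 9.81)
  expect_equal(bf2$n2[1], 9.81 * 1 / (1025 * 10), tolerance = 1e-6)
  expect_true(all(bf2$stable))
})

test_that("a stable profile has non-negative N^2 and input order is irrelevant", {
  scn <- scenario_config("june")
  z <- seq(2, 100, 2)
  tp <- scenario_profile(scn, z, "temperature")
  bf <- buoyancy_frequency(z, tp, 35.15)
  expect_true(all(bf$n2 >= -1e-12))
  expect_gt(max(bf$n2[bf$depth > 20 & bf$depth < 45]), 1e-4)
  expect_lt(max(abs(bf$n2[bf$depth < 10])), 1e-5)

  o <- sample(length(z))
  bf_shuffled <- buoyancy_frequency(z[o], tp[o], 35.15)
  expect_equal(bf_shuffled, bf)
})

test_that("single-level N^2 input errors", {
  expect_error(buoyancy_frequency(10, 12, 35), "two depth levels")
})

test_that("layer identification recovers scenario ground truth within 5 m", {
  for (nm in c("june", "august")) {
    scn <- scenario_config(nm)
    prof <- gen_profiles(scn, seed = 3)
    lay <- identify_layers(prof$ctd$depth, prof$ctd$temperature)
    expect_true(lay$has_thermocline)
    expect_lt(abs(lay$sml_depth - scn$sml_depth), 5)
    expect_lt(abs(lay$thickness - scn$thermocline_thickness), 5)
  }
})

test_that("layer recovery holds across a scenario grid with noisy profiles", {
  set.seed(55)
  for (sml in c(10, 25, 45)) for (th in c(20, 35, 50)) {
    scn <- scenario_config("custom", sml_depth = sml,
                           thermocline_thickness = th, delta_t = 6,
                           o2_max_depth = sml + th / 2)
    prof <- gen_profiles(scn, depths = seq(1, 120, 1),
                         seed = sample.int(1e6, 1))
    lay <- identify_layers(prof$ctd$depth, prof$ctd$temperature)
    expect_lt(abs(lay$sml_depth - sml), 5)
    expect_lt(abs(lay$thickness - th), 5)
  }
})

test_that("an isothermal profile is flagged as having no thermocline", {
  lay <- identify_layers(1:100, rep(12, 100) + rnorm(100, 0, 0.01))
  expect_false(lay$has_thermocline)
  expect_error(gradient_bulk(1, 2, lay), "no thermocline")
})

test_that("zero-noise profiles give near-exact layer recovery", {
  scn <- scenario_config("june")
  prof <- gen_profiles(scn, noise = FALSE)
  lay <- identify_layers(prof$ctd$depth, prof$ctd$temperature)
  expect_lt(abs(lay$sml_depth - 15), 1.5)
  expect_lt(abs(lay$thermocline_bottom - 50), 1.5)
})

test_that("direct gradient is the local least-squares slope", {
  z <- 1:100
  expect_equal(gradient_direct(z, 0.25 * z, 50, window = 10)$value, 0.25,
               tolerance = 1e-12)
  expect_equal(gradient_direct(z, rep(7, 100), 50, window = 10)$value, 0,
               tolerance = 1e-12)
  expect_error(gradient_direct(c(1, 2, 50), c(1, 2, 3), 80, window = 4),
               "bulk")
})

test_that("June-like NOx gradient across the thermocline is ~0.257 mmol m^-4", {
  scn <- scenario_config("june")
  z <- seq(1, 100, 1)
  nox <- scenario_profile(scn, z, "nox")
  g <- gradient_direct(z, nox, centre_depth = 32.5, window = 10)
  expect_equal(g$value, 9 / 35, tolerance = 0.01)
})

test_that("bulk gradient divides the layer difference by the thickness", {
  lay <- identify_layers(1:100, scenario_profile(scenario_config("june"),
                                                 1:100, "temperature"))
  g <- gradient_bulk(0, 70, lay)        # DIC-like step of 70 over ~35 m
  expect_equal(g$value, 70 / lay$thickness, tolerance = 1e-12)
  expect_equal(g$value, 2.0, tolerance = 0.1)
  expect_equal(gradient_bulk(5, 5, lay)$value, 0)
})

test_that("bulk and direct gradients agree on a linear thermocline", {
  scn <- scenario_config("june")
  z <- seq(1, 100, 0.5)
  nox <- scenario_profile(scn, z, "nox")
  lay <- identify_layers(z, scenario_profile(scn, z, "temperature"))
  gb <- gradient_bulk(mean(nox[z <= lay$sml_depth]),
                      mean(nox[z >= lay$deep_top]), lay)
  gd <- gradient_direct(z, nox, (lay$thermocline_top + lay$thermocline_bottom) / 2,
                        window = 10)
  expect_equal(gb$value, gd$value, tolerance = 0.01)
})

test_that("oxygen saturation uses the solubility fit", {
  sol <- o2_solubility(12, 35.2, "mmol_m3")
  expect_equal(o2_saturation(sol, 12, 35.2), 100, tolerance = 1e-10)
  expect_equal(o2_saturation(0, 12, 35.2), 0)
  # June scenario: oversaturated SML, deep-water deficit
  scn <- scenario_config("june")
  t_sml <- scenario_profile(scn, 5, "temperature")
  t_deep <- scenario_profile(scn, 80, "temperature")
  expect_gt(o2_saturation(scn$o2_sml, t_sml, scn$salinity), 100)
  expect_lt(o2_saturation(scn$o2_deep, t_deep, scn$salinity), 100)
})
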