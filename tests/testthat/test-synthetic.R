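test_that("generators are bit-identical under a fixed seed", {
  expect_identical(gen_burst(1e-7, seed = 4), gen_burst(1e-7, seed = 4))
  scn <- scenario_config("june")
  expect_identical(gen_profiles(scn, seed = 4), gen_profiles(scn, seed = 4))
  expect_identical(gen_mooring(scn, seed = 4), gen_mooring(scn, seed = 4))
  expect_identical(gen_currents(seed = 4), gen_currents(seed = 4))
})

test_that("june and august presets carry the scenario's profile anchors", {
  j <- scenario_config("june")
  expect_equal(scenario_profile(j, 5, "oxygen"), 252, tolerance = 1e-3)
  expect_equal(scenario_profile(j, j$o2_max_depth, "oxygen"), 273)
  expect_equal(scenario_profile(j, 90, "oxygen"), 262, tolerance = 1e-6)
  expect_equal(scenario_profile(j, 5, "nox"), 0)
  expect_equal(scenario_profile(j, 90, "nox"), 9)
  expect_equal(scenario_profile(j, 90, "dic") - scenario_profile(j, 5, "dic"),
               70)
  expect_equal(j$sml_depth, 15)
  expect_equal(j$thermocline_thickness, 35)

  a <- scenario_config("august")
  expect_equal(a$sml_depth, 40)
  expect_equal(scenario_profile(a, 95, "oxygen"), 240, tolerance = 1e-6)
  expect_gt(a$sml_depth, j$sml_depth)
})

test_that("epsilon ground truth is calibrated so Kz x gradient hits the targets", {
  for (nm in c("june", "august")) {
    scn <- scenario_config(nm)
    tr <- scn$truth
    for (row in scn$flux_rows) {
      if (!isTRUE(row$calibrates)) next
      expect_equal(abs(tr$fluxes[[row$quantity]]), row$target,
                   tolerance = 1e-10)
    }
    # Kz = Gamma eps / N2 by construction
    for (d in names(tr$epsilon))
      expect_equal(tr$kz[[d]], tr$gamma * tr$epsilon[[d]] / tr$n2_thermocline,
                   tolerance = 1e-12)
  }
})

test_that("a zero-epsilon noise-only burst has a flat structure function at 2 sigma^2", {
  cfg <- adcp_config(burst_samples = 2000L)
  b <- gen_burst(0, cfg, noise_sd = 0.0061, seed = 6)
  sf <- structure_function(b, cfg)
  dll_mid <- sf[[1]]$dll[16, ]
  expect_equal(dll_mid, rep(2 * 0.0061^2, length(dll_mid)), tolerance = 0.1)
})

test_that("mooring series matches the scenario's thermocline N^2 within 5%", {
  scn <- scenario_config("june")
  m <- gen_mooring(scn, days = 1, seed = 5)
  expect_length(m$depths, 23L)
  expect_equal(as.numeric(difftime(m$time[2], m$time[1], units = "mins")), 5)
  n2 <- n2_band(m$depths, rowMeans(m$temperature), rowMeans(m$salinity),
                band = c(scn$sml_depth + 3,
                         scn$sml_depth + scn$thermocline_thickness - 3))
  expect_equal(n2, scn$truth$n2_thermocline, tolerance = 0.05)
})

test_that("a june-to-august drift deepens the SML linearly", {
  j <- scenario_config("june"); a <- scenario_config("august")
  m <- gen_mooring(j, days = 63, end_scenario = a, dt_min = 720, noise_t = 0,
                   seed = 2)
  # SML depth proxy: shallowest mooring level more than 0.5 C colder than top
  sml_of <- function(col) {
    t <- m$temperature[, col]
    m$depths[which(t < t[1] - 0.5)[1]]
  }
  first <- sml_of(1); last <- sml_of(ncol(m$temperature))
  expect_lt(abs(first - 15), 6)
  expect_gt(last, 38)
  mid <- sml_of(round(ncol(m$temperature) / 2))
  expect_lt(abs(mid - (first + last) / 2), 6)
})

test_that("M2+S2 currents beat at the 14.77-day spring-neap period", {
  cur <- gen_currents(days = 35, seed = 3)
  expect_equal(cur$truth$spring_neap_days, 14.77, tolerance = 1e-3)
  # envelope of the barotropic speed: daily max
  day <- floor(as.numeric(cur$time - cur$time[1]) / 86400)
  env <- tapply(cur$u47, day, max)
  dnum <- as.numeric(names(env))
  d1 <- dnum[which.max(env)]
  far <- abs(dnum - d1) >= 7          # skip the rest of the same spring
  d2 <- dnum[far][which.max(env[far])]
  sep <- abs(d2 - d1)
  expect_true(abs(sep - 14.77) < 2 || abs(sep - 29.54) < 2)
  # neap minimum well below spring maximum (equal amplitudes would cancel)
  expect_lt(min(env), 0.45 * max(env))
})

test_that("wind events inject clockwise inertial shear confined near the surface", {
  cur <- gen_currents(days = 14, seed = 7)
  band <- band_definition()
  amp_at <- function(z0) {
    sh <- shear_at_depth(cur$depths, cur$u, cur$v, z0)
    ba <- band_amplitude(rotary_spectrum(cur$time, sh), band)
    max(ba$inertial_amp)
  }
  a16 <- amp_at(16); a47 <- amp_at(47)
  expect_gt(a16, 3 * a47)

  quiet <- gen_currents(days = 14, seed = 7,
                        wind_events = data.frame(start_day = numeric(0),
                                                 amp = numeric(0),
                                                 wind_speed = numeric(0),
                                                 duration_days = numeric(0)))
  a16_quiet <- {
    sh <- shear_at_depth(quiet$depths, quiet$u, quiet$v, 16)
    max(band_amplitude(rotary_spectrum(quiet$time, sh), band)$inertial_amp)
  }
  expect_gt(a16, 20 * a16_quiet)
})

test_that("the inertial 16 m / 47 m shear ratio matches the prescribed decay", {
  # noise-free currents so the spectral ratio isolates the depth structure
  cur <- gen_currents(days = 14, seed = 1, noise = 0,
                      m2_amp = 0, s2_amp = 0)
  band <- band_definition()
  amp_at <- function(z0) {
    sh <- shear_at_depth(cur$depths, cur$u, cur$v, z0)
    ba <- band_amplitude(rotary_spectrum(cur$time, sh), band)
    max(ba$inertial_amp)
  }
  # analytic slab-shear amplitude of the prescribed vertical profile
  slab_shear <- function(z0) {
    g <- cur$truth$inertial_profile
    zz <- cur$depths
    abs(mean(g(zz[zz >= z0 - 10 & zz <= z0])) -
          mean(g(zz[zz > z0 & zz <= z0 + 10]))) / 10
  }
  want <- (slab_shear(16) / slab_shear(47))^2   # spectra are amplitude^2
  got <- amp_at(16) / amp_at(47)
  expect_equal(got, want, tolerance = 0.2)
})

test_that("wave contamination would alias if the period is too short", {
  expect_error(gen_burst(1e-7, wave_amp = 0.01, wave_period = 1.5), "alias")
})
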