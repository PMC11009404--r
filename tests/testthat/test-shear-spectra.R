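make_times <- function(n, dt_hours = 0.5)
  as.POSIXct("2014-07-01", tz = "UTC") + (0:(n - 1)) * dt_hours * 3600

test_that("slab shear is exact for depth-linear and depth-uniform flow", {
  depths <- seq(2, 80, 2)
  nt <- 5
  s <- 0.013
  u <- matrix(s * depths, length(depths), nt)
  v <- matrix(0.1, length(depths), nt)
  sh <- shear_at_depth(depths, u, v, z0 = 35)
  expect_equal(Re(sh), rep(-s, nt), tolerance = 1e-12)   # above minus below
  expect_equal(Im(sh), rep(0, nt), tolerance = 1e-12)

  u0 <- matrix(0.2, length(depths), nt)
  expect_equal(shear_at_depth(depths, u0, u0, 35), rep(0 + 0i, nt))
  expect_error(shear_at_depth(depths, u, v, 75), "cover")
})

test_that("a surface-confined inertial slab gives |shear| = |u|/dz, clockwise", {
  depths <- seq(2, 60, 2)
  tt <- make_times(48)
  td <- as.numeric(tt - tt[1]) / 86400
  f_cpd <- 1.52
  amp <- 0.2
  w <- amp * exp(-1i * 2 * pi * f_cpd * td)
  u <- outer(as.numeric(depths <= 20), Re(w))
  v <- outer(as.numeric(depths <= 20), Im(w))
  sh <- shear_at_depth(depths, u, v, z0 = 20)
  expect_equal(Mod(sh), rep(amp / 10, length(td)), tolerance = 1e-10)
  # clockwise: phase decreases with time
  dphi <- diff(Arg(sh))
  dphi[dphi > pi] <- dphi[dphi > pi] - 2 * pi
  expect_true(all(dphi < 0))
})

test_that("rotary spectra separate pure rotations and obey Parseval", {
  n <- 168
  tt <- make_times(n)
  td <- as.numeric(tt - tt[1]) / 86400
  f <- 2.0                         # on the 1/3.5 cpd grid
  cw_series <- exp(-1i * 2 * pi * f * td)
  sp <- rotary_spectrum(tt, cw_series, taper = "none")
  w1 <- sp$windows[[1]]
  j <- which.min(abs(w1$freq_cpd - f))
  expect_gt(w1$cw[j] / sum(w1$acw), 1e6)       # all variance clockwise at f
  expect_equal(w1$cw[j], 1, tolerance = 1e-10) # unit-amplitude rotation

  rs <- cos(2 * pi * f * td)                   # real sinusoid: equal CW/ACW
  w2 <- rotary_spectrum(tt, rs + 0i, taper = "none")$windows[[1]]
  expect_equal(w2$cw[j], w2$acw[j], tolerance = 1e-10)

  set.seed(8)
  x <- complex(real = rnorm(n), imaginary = rnorm(n))
  w3 <- rotary_spectrum(tt, x, taper = "none")$windows[[1]]
  xs <- x - mean(x)
  expect_equal(sum(w3$cw) + sum(w3$acw), mean(Mod(xs)^2),
               tolerance = 1e-10)
})

test_that("conjugating the series swaps CW and ACW exactly", {
  n <- 168
  tt <- make_times(n)
  set.seed(13)
  x <- complex(real = rnorm(n), imaginary = rnorm(n))
  a <- rotary_spectrum(tt, x, taper = "none")$windows[[1]]
  b <- rotary_spectrum(tt, Conj(x), taper = "none")$windows[[1]]
  jmax <- floor((n - 1) / 2)       # the unsigned Nyquist bin is excluded
  expect_equal(a$cw[1:jmax], b$acw[1:jmax], tolerance = 1e-12)
  expect_equal(a$acw[1:jmax], b$cw[1:jmax], tolerance = 1e-12)
})

test_that("two-line series recovers bin variances against a direct DFT oracle", {
  n <- 168
  tt <- make_times(n)
  td <- as.numeric(tt - tt[1]) / 86400
  x <- 0.3 * exp(-1i * 2 * pi * 1.52 * td) +      # CW inertial, off-grid
    0.1 * cos(2 * pi * 1.97 * td)                 # mixed tidal
  w <- rotary_spectrum(tt, x, taper = "none")$windows[[1]]
  # brute-force DFT oracle
  xs <- x - mean(x)
  dft <- vapply(seq_len(n) - 1L, function(k)
    abs(sum(xs * exp(-2i * pi * k * (seq_len(n) - 1L) / n)))^2 / n^2,
    numeric(1))
  jmax <- floor((n - 1) / 2)
  expect_equal(w$acw[1:jmax], dft[2:(jmax + 1)], tolerance = 1e-12)
  expect_equal(w$cw[1:jmax], dft[n:(n - jmax + 1)], tolerance = 1e-12)
})

test_that("band extraction picks the nearest grid frequency", {
  # 3.5-day grid: nearest bin to 1.52 cpd is 5/3.5 = 1.4286; to 1.97 is 7/3.5 = 2
  grid <- (1:30) / 3.5
  expect_equal(which.min(abs(grid - 1.52)), 5L)
  expect_equal(which.min(abs(grid - 1.97)), 7L)

  n <- 168
  tt <- make_times(n)
  td <- as.numeric(tt - tt[1]) / 86400
  x <- 0.4 * exp(-1i * 2 * pi * 2.0 * td)       # exactly on the tidal bin
  ba <- band_amplitude(rotary_spectrum(tt, x, taper = "none"),
                       band_definition())
  expect_equal(ba$tidal_amp[1], 0.4^2, tolerance = 1e-10)
  ba0 <- band_amplitude(rotary_spectrum(tt, rep(0 + 0i, n), taper = "none"),
                        band_definition())
  expect_equal(ba0$inertial_amp, 0)
  expect_equal(ba0$tidal_amp, 0)
})

test_that("Rayleigh separability matches |f1-f2|*T >= 1", {
  expect_true(rayleigh_separable(3.5, 1.52, 1.97))   # 1.575 >= 1
  expect_false(rayleigh_separable(2.0, 1.52, 1.97))  # 0.9 < 1
  expect_false(rayleigh_separable(10, 1.5, 1.5))
  expect_true(band_definition()$rayleigh_ok)
})

test_that("inertial frequency follows 2 Omega sin(latitude)", {
  expect_equal(inertial_frequency(90)$period_h, 11.97, tolerance = 1e-3)
  expect_equal(inertial_frequency(30)$period_h, 23.93, tolerance = 1e-3)
  i49 <- inertial_frequency(49.2)
  expect_equal(i49$period_h, 15.80, tolerance = 1e-2)
  expect_equal(i49$cpd, 1.52, tolerance = 2e-3)
  expect_error(inertial_frequency(0), "equator")
})

test_that("effective tidal period averages the constituents", {
  expect_equal(effective_tidal_period(c(12.4206, 12.0000)), 12.2103)
  expect_equal(effective_tidal_period(11), 11)
  expect_equal(effective_tidal_period(c(12, 12)), 12)
})

test_that("forcing proxies apply the 24 h running mean and thresholds", {
  n <- 96
  tt <- make_times(n)
  fp <- forcing_proxies(tt, rep(0.4, n), rep(0, n), rep(0, n))
  expect_equal(fp$u47_cubed, rep(0.064, n), tolerance = 1e-12)
  expect_true(all(fp$tide_strong))
  expect_false(any(fp$wind_strong))
  expect_equal(fp$wind_power, rep(0, n))

  fp2 <- forcing_proxies(tt, rep(0, n), rep(10, n),
                         rep(bulk_wind_stress(10), n))
  expect_equal(fp2$wind_power[1], 1.59, tolerance = 0.01)
  expect_false(any(fp2$wind_strong))
  fp3 <- forcing_proxies(tt, rep(0, n), rep(14, n),
                         rep(bulk_wind_stress(14), n))
  expect_true(all(fp3$wind_strong))
})
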