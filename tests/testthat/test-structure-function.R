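test_that("structure function matches brute-force pair enumeration", {
  cfg <- tiny_config()
  set.seed(21)
  v <- array(rnorm(2 * 10 * 50, sd = 0.01), dim = c(2, 10, 50))
  b <- adcp_burst(v, config = cfg)
  # also exercise masked cells
  b$qc_mask[1, 4, 1:10] <- TRUE
  b$qc_mask[2, 9, ] <- TRUE
  got <- structure_function(b, cfg)
  want <- brute_force_dll(b, cfg)
  for (beam in 1:2)
    expect_equal(got[[beam]]$dll, want[[beam]], tolerance = 1e-14)
})

test_that("constant and pure-shear fields give analytic structure functions", {
  cfg <- tiny_config()
  b <- adcp_burst(array(0.3, dim = c(2, 10, 50)), config = cfg)
  sf <- structure_function(b, cfg)
  expect_true(all(sf[[1]]$dll[is.finite(sf[[1]]$dll)] == 0))

  s <- 0.05
  z <- bin_centres(cfg)
  v <- array(rep(s * z, each = 2), dim = c(2, 10, 50))
  sfs <- structure_function(adcp_burst(v, config = cfg), cfg)
  for (k in seq_along(sfs[[1]]$separations)) {
    r <- sfs[[1]]$separations[k]
    vals <- sfs[[1]]$dll[, k]
    expect_equal(vals[is.finite(vals)],
                 rep(s^2 * r^2, sum(is.finite(vals))), tolerance = 1e-12)
  }
})

test_that("sampled Kolmogorov bursts track C2 eps^(2/3) r^(2/3)", {
  cfg <- adcp_config(burst_samples = 1000L)
  eps <- 1e-7
  b <- gen_burst(eps, cfg, noise_sd = 0, seed = 3)
  sf <- structure_function(b, cfg)
  r <- sf[[1]]$separations
  theory <- cfg$c2 * eps^(2 / 3) * r^(2 / 3)
  mid_bin <- 16
  expect_equal(sf[[1]]$dll[mid_bin, ], theory, tolerance = 0.15)
})

test_that("velocity scaling lambda scales D_LL by lambda^2 and eps by lambda^3", {
  cfg <- tiny_config()
  set.seed(5)
  v <- array(rnorm(2 * 10 * 50, sd = 0.02), dim = c(2, 10, 50))
  lam <- 3
  sf1 <- structure_function(adcp_burst(v, config = cfg), cfg)
  sf2 <- structure_function(adcp_burst(lam * v, config = cfg), cfg)
  expect_equal(sf2[[1]]$dll, lam^2 * sf1[[1]]$dll, tolerance = 1e-12)

  f1 <- fit_modified(sf1[[1]]$separations, sf1[[1]]$dll[5, ])
  f2 <- fit_modified(sf2[[1]]$separations, sf2[[1]]$dll[5, ])
  expect_equal(f2$a1, lam^2 * f1$a1, tolerance = 1e-10)
  if (f1$a1 > 0)
    expect_equal(epsilon_from_fit(f2$a1), lam^3 * epsilon_from_fit(f1$a1),
                 tolerance = 1e-10)
})

test_that("three-term regression recovers exact model members", {
  r <- 0.2 * (1:8)
  x <- r^(2 / 3)
  # pure Kolmogorov member
  f <- fit_modified(r, 2.1e-5 * x)
  expect_equal(f$a0, 0, tolerance = 1e-18)
  expect_equal(f$a1, 2.1e-5, tolerance = 1e-12)
  expect_equal(f$a3, 0, tolerance = 1e-12)
  # pure r^2 contamination
  g <- fit_modified(r, 0.05^2 * r^2)
  expect_equal(g$a1, 0, tolerance = 1e-12)
  expect_equal(g$a3, 2.5e-3, tolerance = 1e-9)
  # superposition, checked against lm() as an independent least-squares oracle
  y <- 3e-5 + 2.1e-5 * x + 2.5e-3 * r^2
  h <- fit_modified(r, y)
  o <- unname(coef(lm(y ~ x + I(x^3))))
  expect_equal(c(h$a0, h$a1, h$a3), o, tolerance = 1e-9)
  expect_equal(h$a1, 2.1e-5, tolerance = 1e-9)
  expect_equal(h$a3, 2.5e-3, tolerance = 1e-7)
})

test_that("degenerate regressions are flagged, not fitted", {
  expect_false(fit_modified(c(0.2, 0.2, 0.2), c(1, 2, 3) * 1e-5)$ok)
  expect_false(fit_modified(c(0.2, 0.4), c(1, 2) * 1e-5)$ok)
})

test_that("screening rules follow the exclusion list with inclusive a0 bounds", {
  ok <- list(a0 = 1e-5, a1 = 2e-5, a3 = 1e-6, n_points = 10, ok = TRUE)
  expect_true(screen_fit(ok)$valid)

  bad_a3 <- ok; bad_a3$a3 <- -1e-9
  expect_false(screen_fit(bad_a3)$valid)
  expect_equal(screen_fit(bad_a3)$reason, "a3<0")

  edge <- list(a0 = 3e-4, a1 = 2e-5, a3 = 0, n_points = 8, ok = TRUE)
  expect_true(screen_fit(edge)$valid)          # bounds inclusive
  edge$a0 <- -1e-4
  expect_true(screen_fit(edge)$valid)
  edge$a0 <- 3.0001e-4
  expect_false(screen_fit(edge)$valid)

  few <- ok; few$n_points <- 7
  expect_false(screen_fit(few)$valid)
  expect_equal(screen_fit(few)$reason, "too few points")

  neg_a1 <- ok; neg_a1$a1 <- -1e-6
  expect_false(screen_fit(neg_a1)$valid)
})

test_that("stricter screening never increases the number of valid fits", {
  set.seed(31)
  fits <- replicate(200, list(a0 = rnorm(1, 5e-5, 1e-4),
                              a1 = rnorm(1, 2e-5, 3e-5),
                              a3 = rnorm(1, 0, 1e-4),
                              n_points = sample(5:15, 1), ok = TRUE),
                    simplify = FALSE)
  n_valid <- function(a0_max, min_points)
    sum(vapply(fits, function(f)
      screen_fit(f, a0_max = a0_max, min_points = min_points)$valid,
      logical(1)))
  expect_gte(n_valid(3e-4, 8), n_valid(2e-4, 8))
  expect_gte(n_valid(3e-4, 8), n_valid(3e-4, 10))
  expect_gte(n_valid(2e-4, 8), n_valid(2e-4, 12))
})

test_that("epsilon follows (a1/C2)^(3/2)", {
  expect_equal(epsilon_from_fit(0), 0)
  expect_equal(epsilon_from_fit(2.1, c2 = 2.1), 1)
  expect_equal(epsilon_from_fit(4.52e-5, c2 = 2.1), 1e-7, tolerance = 2e-3)
  expect_error(epsilon_from_fit(-1e-6), "screened")
})
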