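#' Seawater density at atmospheric pressure
#'
#' International one-atmosphere equation of state of seawater (EOS-80;
#' Millero & Poisson 1981, as tabulated by UNESCO Technical Papers in
#' Marine Science 44). Accurate to much better than 1e-2 kg m^-3 over the
#' oceanographic range, which is ample for buoyancy-frequency work across a
#' seasonal thermocline.
#'
#' Check values (pinned in the test suite): rho(S=0, T=5) = 999.96675,
#' rho(S=35, T=5) = 1027.67547, rho(S=35, T=25) = 1023.34306 kg m^-3.
#'
#' @param salinity Practical salinity (PSS-78).
#' @param temperature In-situ temperature, degrees C.
#' @return Density, kg m^-3.
#' @export
sw_density <- function(salinity, temperature) {
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rho_w + A * s + B * s^1.5 + C * s^2
}

#' Buoyancy frequency squared from a temperature/salinity profile
#'
#' \deqn{N^2 = \frac{g}{\rho_0} \frac{\partial \rho}{\partial z}}
#' with depth z positive downward, so a density-stable profile (density
#' increasing with depth) gives \eqn{N^2 \ge 0}. Density comes from
#' [sw_density()] and the derivative uses centred differences on the native
#' (sorted) grid, one-sided at the ends. Inversions are returned as
#' negative values with `stable = FALSE`, never clipped.
#'
#' @param depth Depths, m, positive downward (any order; sorted internally).
#' @param temperature,salinity Profile values at `depth`.
#' @param rho0 Reference density, kg m^-3.
#' @param g Gravitational acceleration, m s^-2.
#'
#' @return Data frame `depth`, `n2` (s^-2), `stable`.
#' @export
buoyancy_frequency <- function(depth, temperature, salinity = 35,
                               rho0 = 1025, g = 9.81) {
  if (length(depth) < 2) stop("at least two depth levels are required")
  if (length(salinity) == 1) salinity <- rep(salinity, length(depth))
  o <- order(depth)
  depth <- depth[o]; temperature <- temperature[o]; salinity <- salinity[o]
  rho <- sw_density(salinity, temperature)
  n <- length(depth)
  drho_dz <- numeric(n)
  drho_dz[1] <- (rho[2] - rho[1]) / (depth[2] - depth[1])
  drho_dz[n] <- (rho[n] - rho[n - 1]) / (depth[n] - depth[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    drho_dz[i] <- (rho[i + 1] - rho[i - 1]) / (depth[i + 1] - depth[i - 1])
  }
  n2 <- g / rho0 * drho_dz
  data.frame(depth = depth, n2 = n2, stable = n2 >= 0)
}

#' Mean stratification over a depth band
#'
#' Convenience wrapper: mean \eqn{N^2} from [buoyancy_frequency()] over
#' `band = c(zmin, zmax)`. For mooring time series, pass the time-mean
#' temperature/salinity profile.
#'
#' @inheritParams buoyancy_frequency
#' @param band Numeric length-2 depth band, m.
#' @return Mean \eqn{N^2}, s^-2.
#' @export
n2_band <- function(depth, temperature, salinity = 35, band,
                    rho0 = 1025, g = 9.81) {
  bf <- buoyancy_frequency(depth, temperature, salinity, rho0, g)
  sel <- bf$depth >= min(band) & bf$depth <= max(band)
  if (!any(sel)) stop("no levels inside the requested depth band")
  mean(bf$n2[sel])
}

#' Oxygen solubility in seawater
#'
#' Equilibrium (100% saturation) dissolved-oxygen concentration at one
#' atmosphere, from the Garcia & Gordon (1992) combined fit to the Benson &
#' Krause data. The fit's own check value, 274.61 umol kg^-1 at T = 10 C,
#' S = 35, is pinned in the test suite to 4 significant figures.
#'
#' @param temperature Temperature, degrees C (valid -2 to 40).
#' @param salinity Practical salinity (valid 0 to 42).
#' @param units `"mmol_m3"` (volumetric, via [sw_density()]) or
#'   `"umol_kg"` (the fit's native units).
#' @return Solubility in the requested units.
#' @export
o2_solubility <- function(temperature, salinity, units = c("mmol_m3", "umol_kg")) {
  units <- match.arg(units)
  if (any(temperature < -2 | temperature > 40))
    stop("temperature outside solubility-fit validity (-2 to 40 C)")
  if (any(salinity < 0 | salinity > 42))
    stop("salinity outside solubility-fit validity (0 to 42)")
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  umol_kg <- exp(lnc)
  if (units == "umol_kg") return(umol_kg)
  umol_kg * sw_density(salinity, temperature) / 1000
}

#' Oxygen saturation
#'
#' Percentage saturation of a measured dissolved-oxygen concentration
#' relative to the equilibrium solubility at the in-situ temperature and
#' salinity.
#'
#' @param oxygen Measured concentration, mmol m^-3.
#' @param temperature Degrees C.
#' @param salinity Practical salinity.
#' @return Saturation, percent.
#' @export
o2_saturation <- function(oxygen, temperature, salinity) {
  100 * oxygen / o2_solubility(temperature, salinity, units = "mmol_m3")
}

#' Schmidt number for oxygen in seawater
#'
#' Fourth-order polynomial in temperature (Wanninkhof 2014, for salinity
#' 35); its tabulated value at 20 C (568) is pinned in the test suite.
#'
#' @param temperature Degrees C (valid -2 to 40).
#' @return Dimensionless Schmidt number.
#' @export
schmidt_o2 <- function(temperature) {
  if (any(temperature < -2 | temperature > 40))
    stop("temperature outside Schmidt-polynomial validity (-2 to 40 C)")
  t <- temperature
  1920.4 - 135.6 * t + 5.2122 * t^2 - 0.10939 * t^3 + 0.00093777 * t^4
}
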