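#' Gas-transfer velocity for a quadratic wind-speed relation
#'
#' \deqn{k = a \, u_{10}^2 \, (Sc/660)^{-1/2}}
#' with the quadratic coefficient a = 0.251 (cm h^-1)/(m s^-1)^2 and the
#' Schmidt number referenced to 660 (CO2 at 20 C in seawater).
#'
#' @param u10 Wind speed at 10 m, m s^-1.
#' @param sc Schmidt number of the gas at the water temperature
#'   (see [schmidt_o2()]).
#' @param k660_coeff Quadratic coefficient, (cm h^-1)/(m s^-1)^2.
#' @param schmidt_ref Reference Schmidt number.
#' @return Transfer velocity, cm h^-1.
#' @export
gas_transfer_velocity <- function(u10, sc, k660_coeff = 0.251,
                                  schmidt_ref = 660) {
  if (any(u10 < 0)) stop("u10 must be non-negative")
  if (any(sc <= 0)) stop("Schmidt number must be positive")
  k660_coeff * u10^2 * (sc / schmidt_ref)^(-0.5)
}

#' Air-sea oxygen flux
#'
#' \deqn{F = k \,(O_2^{surf} - O_2^{sat}(T, S))}
#' Positive flux = outgassing (sea to air); an exactly saturated surface
#' gives zero flux for any wind.
#'
#' @param o2_surface Surface dissolved oxygen, mmol m^-3.
#' @param temperature Surface temperature, degrees C.
#' @param salinity Surface practical salinity.
#' @param u10 Wind speed at 10 m, m s^-1.
#' @param ... Passed to [gas_transfer_velocity()].
#' @return Flux, mmol m^-2 d^-1.
#' @export
airsea_o2_flux <- function(o2_surface, temperature, salinity, u10, ...) {
  k_cm_h <- gas_transfer_velocity(u10, schmidt_o2(temperature), ...)
  k_m_d <- k_cm_h * 24 / 100
  delta <- o2_surface - o2_solubility(temperature, salinity, "mmol_m3")
  k_m_d * delta
}

#' Bulk wind stress with a constant drag coefficient
#'
#' \deqn{\tau = \rho_{air} C_d u_{10}^2}
#' A deliberately simple bulk law used to drive the synthetic forcing and
#' the wind-energy proxy \eqn{W_s \tau_s}; a full bulk-flux algorithm can be
#' substituted wherever a stress series is accepted.
#'
#' @param u10 Wind speed at 10 m, m s^-1.
#' @param air_density Air density, kg m^-3.
#' @param drag_coeff Dimensionless drag coefficient.
#' @return Wind stress, Pa.
#' @export
bulk_wind_stress <- function(u10, air_density = 1.22, drag_coeff = 1.3e-3) {
  if (any(u10 < 0)) stop("u10 must be non-negative")
  air_density * drag_coeff * u10^2
}
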