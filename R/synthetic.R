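#' Synthetic stratified-water-column scenario
#'
#' Defines a complete synthetic study condition - layer structure,
#' biogeochemical profile shapes and the dissipation ground truth - from
#' which every pipeline input can be generated with analytic targets.
#'
#' The `"june"` preset describes early summer: a 15 m surface mixed layer,
#' a 35 m thick thermocline with a 6 C temperature step, an oxygen maximum
#' of 273 mmol m^-3 at 35 m between an oversaturated SML (252) and a deep
#' layer in deficit (262), negligible SML NOx against ~9 umol l^-1 at
#' depth, and a 70 umol kg^-1 DIC step. The `"august"` preset deepens the
#' SML to 40 m, deepens and weakens the oxygen maximum, and lowers deep
#' oxygen to 240 mmol m^-3.
#'
#' The dissipation ground truth per instrument depth is not free: it is
#' calibrated so that \eqn{K_z \times} gradient reproduces the scenario's
#' target fluxes (one calibrating flux per dissipation depth), making the
#' full pipeline a closed loop with known answers.
#'
#' @param name `"june"`, `"august"` or `"custom"`.
#' @param ... Overrides for any field of the preset (see Details).
#'
#' @return An object of class `"scenario_config"`: a list of scenario
#'   fields plus `truth`, a list with `n2_thermocline`, `gradients`,
#'   `epsilon` (named by depth), `kz` and `fluxes` (signed, positive =
#'   downward, mmol m^-2 d^-1).
#' @export
scenario_config <- function(name = c("june", "august", "custom"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    june = list(
      date = as.Date("2014-06-19"),
      sml_depth = 15, thermocline_thickness = 35, delta_t = 6,
      t_deep = 11.5, salinity = 35.15,
      o2_sml = 252, o2_max = 273, o2_deep = 262, o2_max_depth = 35,
      o2_sigma = 8,
      nox_sml = 0, nox_deep = 9,
      dic_sml = 2080, dic_delta = 70,
      chl_max = 3, chl_bg = 0.2,
      noise_t = 0.05, noise_o2 = 1.0,
      flux_rows = list(
        list(quantity = "NOx",     eps_depth = 36, target = 2.8,  calibrates = TRUE),
        list(quantity = "DIC",     eps_depth = 36, target = 20.8, calibrates = FALSE),
        list(quantity = "O2_up",   eps_depth = 16, target = 45.9, calibrates = TRUE),
        list(quantity = "O2_down", eps_depth = 47, target = 4.0,  calibrates = TRUE))),
    august = list(
      date = as.Date("2014-08-21"),
      sml_depth = 40, thermocline_thickness = 35, delta_t = 7.8,
      t_deep = 12.2, salinity = 35.15,
      o2_sml = 234, o2_max = 259, o2_deep = 240, o2_max_depth = 50,
      o2_sigma = 8,
      nox_sml = 0, nox_deep = 9,
      dic_sml = 2080, dic_delta = 70,
      chl_max = 1.5, chl_bg = 0.2,
      noise_t = 0.05, noise_o2 = 1.0,
      flux_rows = list(
        list(quantity = "NOx",     eps_depth = 36, target = 1.9,  calibrates = TRUE),
        list(quantity = "DIC",     eps_depth = 36, target = 10.8, calibrates = FALSE),
        list(quantity = "O2_up",   eps_depth = 36, target = 6.5,  calibrates = FALSE),
        list(quantity = "O2_down", eps_depth = 47, target = 20.2, calibrates = TRUE))),
    custom = list(
      date = as.Date("2014-07-01"),
      sml_depth = 20, thermocline_thickness = 30, delta_t = 5,
      t_deep = 11.5, salinity = 35.15,
      o2_sml = 250, o2_max = 270, o2_deep = 255, o2_max_depth = 35,
      o2_sigma = 8,
      nox_sml = 0, nox_deep = 9,
      dic_sml = 2080, dic_delta = 70,
      chl_max = 2, chl_bg = 0.2,
      noise_t = 0.05, noise_o2 = 1.0,
      flux_rows = list())
  )
  ov <- list(...)
  base[names(ov)] <- ov
  base$name <- name
  scn <- structure(base, class = "scenario_config")
  scn$truth <- scenario_truth(scn)
  scn
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s (%s): SML %g m, thermocline %g m thick, dT %g C\n",
              x$name, format(x$date), x$sml_depth, x$thermocline_thickness,
              x$delta_t))
  if (length(x$truth$epsilon))
    cat("  epsilon truth (W kg^-1):",
        paste(sprintf("%s m: %.3g", names(x$truth$epsilon), x$truth$epsilon),
              collapse = ", "), "\n")
  invisible(x)
}

# fractional position across the thermocline (0 in SML, 1 in deep layer)
scenario_ramp <- function(scn, z) {
  pmin(pmax((z - scn$sml_depth) / scn$thermocline_thickness, 0), 1)
}

#' Analytic scenario profiles
#'
#' Noise-free profile values at arbitrary depth for a
#' [scenario_config()]: the analytic curves the generators sample from.
#'
#' @param scn A `"scenario_config"`.
#' @param z Depths, m.
#' @param what One of `"temperature"`, `"oxygen"`, `"chlorophyll"`,
#'   `"nox"`, `"dic"`.
#' @return Numeric vector of profile values.
#' @export
scenario_profile <- function(scn, z,
                             what = c("temperature", "oxygen", "chlorophyll",
                                      "nox", "dic")) {
  what <- match.arg(what)
  f <- scenario_ramp(scn, z)
  switch(what,
    temperature = scn$t_deep + scn$delta_t * (1 - f),
    nox = scn$nox_sml + (scn$nox_deep - scn$nox_sml) * f,
    dic = scn$dic_sml + scn$dic_delta * f,
    chlorophyll = scn$chl_bg +
      scn$chl_max * exp(-(z - scn$o2_max_depth)^2 / (2 * scn$o2_sigma^2)),
    oxygen = {
      bg <- scn$o2_sml + (scn$o2_deep - scn$o2_sml) * f
      bg_at_max <- scn$o2_sml + (scn$o2_deep - scn$o2_sml) *
        scenario_ramp(scn, scn$o2_max_depth)
      amp <- scn$o2_max - bg_at_max
      bg + amp * exp(-(z - scn$o2_max_depth)^2 / (2 * scn$o2_sigma^2))
    })
}

# analytic ground truth: stratification, gradients, calibrated epsilon, fluxes
scenario_truth <- function(scn, gamma = 0.2, rho0 = 1025, g = 9.81) {
  top <- scn$sml_depth
  bot <- scn$sml_depth + scn$thermocline_thickness
  th <- scn$thermocline_thickness
  # interior N^2 of the linear thermocline (exact for the piecewise profile)
  t_up <- scenario_profile(scn, top + 1, "temperature")
  t_dn <- scenario_profile(scn, bot - 1, "temperature")
  n2 <- g / rho0 *
    (sw_density(scn$salinity, t_dn) - sw_density(scn$salinity, t_up)) /
    (bot - top - 2)

  grads <- list(
    nox = (scn$nox_deep - scn$nox_sml) / th,                  # mmol m^-4
    dic = dic_to_volumetric(scn$dic_delta / th, rho0),        # mmol m^-4
    o2_up = (scn$o2_max - scn$o2_sml) / (scn$o2_max_depth - top),
    o2_down = (scn$o2_deep - scn$o2_max) / (bot - scn$o2_max_depth),
    dTdz = -scn$delta_t / th)

  grad_for <- function(q) switch(q, NOx = grads$nox, DIC = grads$dic,
                                 O2_up = grads$o2_up, O2_down = grads$o2_down)
  eps <- c("16" = 1e-6, "36" = 1e-7, "47" = 1e-7)   # defaults if uncalibrated
  for (row in scn$flux_rows) {
    if (!isTRUE(row$calibrates)) next
    kz_needed <- row$target / (abs(grad_for(row$quantity)) * 86400)
    eps[as.character(row$eps_depth)] <- kz_needed * n2 / gamma
  }
  kz <- gamma * eps / n2
  fluxes <- list()
  for (row in scn$flux_rows) {
    fluxes[[row$quantity]] <-
      -kz[[as.character(row$eps_depth)]] * grad_for(row$quantity) * 86400
  }
  list(n2_thermocline = n2, gradients = grads, epsilon = eps, kz = kz,
       fluxes = fluxes, gamma = gamma)
}

#' Generate a synthetic ADCP burst with known dissipation
#'
#' Along-beam velocity profiles are drawn, per sample and beam, from a
#' Gaussian random field with fractional-Brownian covariance (Hurst
#' exponent 1/3) variance-matched so that spatial increments satisfy the
#' Kolmogorov scaling \eqn{\langle \Delta v^2 \rangle = C_2 \epsilon^{2/3}
#' r^{2/3}}. Samples are independent realizations (no within-burst
#' temporal correlation - sufficient for structure-function statistics,
#' which pool over samples). Additive white instrument noise, a steady
#' linear shear and a wave-like oscillating linear shear (period shorter
#' than the burst) can be superimposed; the latter two are the
#' contamination that produces the \eqn{r^2} term targeted by the
#' three-term regression.
#'
#' @param epsilon_true Prescribed dissipation, W kg^-1 (>= 0).
#' @param config An [adcp_config()].
#' @param shear Steady linear shear, s^-1.
#' @param wave_amp Wave velocity amplitude at the profile edges, m s^-1.
#' @param wave_period Wave period, s (must exceed two sample intervals).
#' @param noise_sd Instrument noise, m s^-1 (defaults to the config's
#'   single-ping standard deviation).
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param timestamp Burst timestamp.
#' @return An [adcp_burst()] with clean correlation and echo fields.
#' @export
gen_burst <- function(epsilon_true, config = adcp_config(),
                      shear = 0, wave_amp = 0, wave_period = 10,
                      noise_sd = config$velocity_sd, seed = 1,
                      timestamp = as.POSIXct("2014-06-19 00:00:00",
                                             tz = "UTC")) {
  if (epsilon_true < 0) stop("epsilon_true must be non-negative")
  if (wave_amp != 0 && wave_period <= 2 / config$sample_rate)
    stop("wave_period at or below two sample intervals would alias")
  set.seed(seed)
  nb <- config$n_bins; ns <- config$burst_samples
  z <- bin_centres(config)
  zc <- z - mean(z)
  span <- diff(range(z))
  tt <- (seq_len(ns) - 1L) / config$sample_rate

  L <- NULL
  if (epsilon_true > 0) {
    s2 <- config$c2 * epsilon_true^(2 / 3)   # increment variance at r = 1 m
    H2 <- 2 / 3
    C <- s2 / 2 * (outer(z^H2, rep(1, nb)) + outer(rep(1, nb), z^H2) -
                     abs(outer(z, z, "-"))^H2)
    L <- chol(C + diag(1e-12 * max(diag(C)), nb))
  }

  v <- array(0, dim = c(config$n_beams, nb, ns))
  for (b in seq_len(config$n_beams)) {
    prof <- if (is.null(L)) matrix(0, nb, ns) else
      crossprod(L, matrix(stats::rnorm(nb * ns), nb, ns))
    prof <- prof + shear * zc
    if (wave_amp != 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      prof <- prof + outer(zc / (span / 2),
                           wave_amp * sin(2 * pi * tt / wave_period + phi))
    }
    prof <- prof + stats::rnorm(nb * ns, sd = noise_sd)
    v[b, , ] <- prof
  }
  adcp_burst(v, timestamp = timestamp, config = config)
}

#' Generate synthetic CTD and bottle profiles
#'
#' Samples the analytic [scenario_profile()] curves: temperature with an
#' SML / linear-thermocline / deep structure, oxygen with a Gaussian
#' mid-water maximum, a co-located Gaussian subsurface chlorophyll
#' maximum, and step-like NOx and DIC sampled at 14 and 12 discrete
#' bottle depths.
#'
#' @param scn A [scenario_config()].
#' @param depths CTD depth grid, m.
#' @param noise Add measurement noise (temperature `scn$noise_t`, oxygen
#'   `scn$noise_o2`, proportionate levels elsewhere)?
#' @param seed Integer seed.
#' @return List `ctd` (data frame: depth, temperature, salinity, oxygen,
#'   chlorophyll), `bottles` (data frame: depth, nox, dic; `NA` where a
#'   bottle was not drawn for that analyte) and `scenario`.
#' @export
gen_profiles <- function(scn, depths = seq(1, 100, by = 1), noise = TRUE,
                         seed = 1) {
  set.seed(seed)
  nz <- length(depths)
  jitter <- function(sd) if (noise) stats::rnorm(nz, sd = sd) else 0
  ctd <- data.frame(
    depth = depths,
    temperature = scenario_profile(scn, depths, "temperature") +
      jitter(scn$noise_t),
    salinity = scn$salinity + jitter(0.005),
    oxygen = pmax(scenario_profile(scn, depths, "oxygen") +
                    jitter(scn$noise_o2), 0),
    chlorophyll = pmax(scenario_profile(scn, depths, "chlorophyll") +
                         jitter(0.05), 0))

  nox_depths <- c(2, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 60, 80, 100)
  dic_depths <- c(2, 5, 10, 15, 20, 30, 40, 45, 50, 60, 80, 100)
  all_d <- sort(unique(c(nox_depths, dic_depths)))
  jb <- function(n, sd) if (noise) stats::rnorm(n, sd = sd) else 0
  bottles <- data.frame(
    depth = all_d,
    nox = ifelse(all_d %in% nox_depths,
                 pmax(scenario_profile(scn, all_d, "nox") +
                        jb(length(all_d), 0.05), 0), NA_real_),
    dic = ifelse(all_d %in% dic_depths,
                 scenario_profile(scn, all_d, "dic") +
                   jb(length(all_d), 1.0), NA_real_))
  list(ctd = ctd, bottles = bottles, scenario = scn)
}

#' Generate a synthetic mooring temperature/salinity time series
#'
#' 23 instrument depths with the deployment's banded spacing (5 m in
#' 10-35 m and 54-74 m, 2 m in 37-49 m, 10 m in 89-129 m) at 5-minute
#' cadence. The layer structure can drift linearly toward a second
#' scenario over the record (early-to-late summer transition).
#'
#' @param scn A [scenario_config()] for the start of the record.
#' @param days Record length, days.
#' @param end_scenario Optional `"scenario_config"`; layer parameters
#'   interpolate linearly from `scn` to it over the record.
#' @param dt_min Cadence, minutes.
#' @param noise_t Temperature noise, degrees C.
#' @param seed Integer seed.
#' @return List `time` (POSIXct), `depths` (m), `temperature`,
#'   `salinity` (matrices depth x time).
#' @export
gen_mooring <- function(scn, days = 1, end_scenario = NULL, dt_min = 5,
                        noise_t = 0.02, seed = 1) {
  if (days < 1) stop("days must be >= 1")
  set.seed(seed)
  depths <- c(seq(10, 35, 5), seq(37, 49, 2), seq(54, 74, 5), seq(89, 129, 10))
  nt <- as.integer(days * 24 * 60 / dt_min)
  time <- as.POSIXct(paste(scn$date, "00:00:00"), tz = "UTC") +
    (seq_len(nt) - 1L) * dt_min * 60
  frac <- if (is.null(end_scenario)) rep(0, nt) else
    (seq_len(nt) - 1L) / max(nt - 1L, 1L)

  interp <- function(field) {
    if (is.null(end_scenario)) rep(scn[[field]], nt) else
      scn[[field]] + frac * (end_scenario[[field]] - scn[[field]])
  }
  sml <- interp("sml_depth"); th <- interp("thermocline_thickness")
  dt_c <- interp("delta_t"); tdeep <- interp("t_deep")

  temp <- matrix(NA_real_, length(depths), nt)
  for (j in seq_len(nt)) {
    f <- pmin(pmax((depths - sml[j]) / th[j], 0), 1)
    temp[, j] <- tdeep[j] + dt_c[j] * (1 - f)
  }
  temp <- temp + stats::rnorm(length(temp), sd = noise_t)
  sal <- matrix(scn$salinity, length(depths), nt) +
    stats::rnorm(length(depths) * nt, sd = 0.003)
  list(time = time, depths = depths, temperature = temp, salinity = sal)
}

#' Generate synthetic current profiles and wind forcing
#'
#' The current field is the sum of (a) a semidiurnal tide (M2 + S2,
#' producing the 14.77-day spring-neap beat) whose vertical structure
#' concentrates shear near the thermocline base, and (b) clockwise-rotating
#' near-inertial oscillations injected by discrete wind events, uniform
#' through the surface layer and decaying below its base with a 10 m
#' e-folding, ramping up over `ramp_days` and decaying with a
#' `decay_days` timescale. The matching wind speed/stress series (bulk
#' drag law) is returned for the forcing proxies.
#'
#' @param latitude Latitude, degrees (sets the inertial frequency).
#' @param days Record length, days (>= 7 so at least two spectral windows
#'   fit).
#' @param dt_hours Cadence, hours.
#' @param depths Profile depths, m.
#' @param m2_amp,s2_amp Tidal current amplitudes, m s^-1.
#' @param tide_depth,tide_scale Centre and scale (m) of the logistic
#'   vertical structure of the tidal current.
#' @param sml_base Depth of the surface-layer base for the inertial
#'   response, m.
#' @param efold_m E-folding depth of the inertial amplitude below
#'   `sml_base`, m.
#' @param wind_events Data frame with `start_day`, `amp` (inertial current
#'   amplitude, m s^-1), `wind_speed` (m s^-1), `duration_days`.
#' @param ramp_days,decay_days Inertial ramp-up and decay timescales, days.
#' @param background_wind Background wind speed, m s^-1.
#' @param noise Velocity noise, m s^-1.
#' @param seed Integer seed.
#' @return List `time`, `depths`, `u`, `v` (depth x time, m s^-1),
#'   `u47` (tidal current speed at 47 m), `wind` (data frame: time, speed,
#'   stress) and `truth` (inertial profile function, event table, beat
#'   period, band frequencies).
#' @export
gen_currents <- function(latitude = 49.2, days = 21, dt_hours = 0.5,
                         depths = seq(2, 100, by = 2),
                         m2_amp = 0.45, s2_amp = 0.20,
                         tide_depth = 47, tide_scale = 5,
                         sml_base = 20, efold_m = 10,
                         wind_events = data.frame(
                           start_day = c(3, 12),
                           amp = c(0.25, 0.30),
                           wind_speed = c(14, 16),
                           duration_days = c(1, 1.5)),
                         ramp_days = 0.2, decay_days = 3,
                         background_wind = 5, noise = 0.003, seed = 1) {
  if (days < 7) stop("need at least 7 days (two 3.5-day spectral windows)")
  set.seed(seed)
  nt <- as.integer(days * 24 / dt_hours)
  t_days <- (seq_len(nt) - 1L) * dt_hours / 24
  time <- as.POSIXct("2014-06-19 00:00:00", tz = "UTC") + t_days * 86400

  m2_cpd <- 24 / 12.4206
  s2_cpd <- 24 / 12.0000
  u_baro <- m2_amp * cos(2 * pi * m2_cpd * t_days) +
    s2_amp * cos(2 * pi * s2_cpd * t_days)
  f_tide <- stats::plogis((depths - tide_depth) / tide_scale)

  u <- outer(f_tide, u_baro)
  v <- matrix(0, length(depths), nt)

  g_inert <- function(z) ifelse(z <= sml_base, 1,
                                exp(-(z - sml_base) / efold_m))
  f_cpd <- inertial_frequency(latitude)$cpd
  gz <- g_inert(depths)
  for (e in seq_len(nrow(wind_events))) {
    dt_e <- t_days - wind_events$start_day[e]
    amp_t <- ifelse(dt_e >= 0,
                    wind_events$amp[e] * (1 - exp(-pmax(dt_e, 0) / ramp_days)) *
                      exp(-pmax(dt_e, 0) / decay_days), 0)
    w <- amp_t * exp(-1i * 2 * pi * f_cpd * dt_e)   # clockwise rotation
    u <- u + outer(gz, Re(w))
    v <- v + outer(gz, Im(w))
  }
  u <- u + stats::rnorm(length(u), sd = noise)
  v <- v + stats::rnorm(length(v), sd = noise)

  speed <- rep(background_wind, nt)
  for (e in seq_len(nrow(wind_events))) {
    on <- t_days >= wind_events$start_day[e] &
      t_days <= wind_events$start_day[e] + wind_events$duration_days[e]
    speed[on] <- wind_events$wind_speed[e]
  }
  wind <- data.frame(time = time, speed = speed,
                     stress = bulk_wind_stress(speed))

  beat_days <- 1 / (s2_cpd - m2_cpd)
  list(time = time, depths = depths, u = u, v = v,
       u47 = abs(u_baro),    # barotropic tidal speed (the energy proxy)
       wind = wind,
       truth = list(inertial_profile = g_inert, events = wind_events,
                    spring_neap_days = beat_days, inertial_cpd = f_cpd,
                    tidal_cpd = (m2_cpd + s2_cpd) / 2))
}
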