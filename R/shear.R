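#' Vertical shear of horizontal currents at a target depth
#'
#' The complex horizontal velocity \eqn{u + iv} is averaged over two 10 m
#' slabs, one above (`[z0 - 10, z0]`) and one below (`(z0, z0 + 10]`) the
#' target depth (a grid point exactly at `z0` belongs to the upper slab
#' only), and the shear is the slab-mean difference divided by the
#' slab-centre separation (10 m with the default slabs).
#'
#' @param depths Profile depths, m, positive downward.
#' @param u,v Velocity components, matrices depth x time, m s^-1.
#' @param z0 Target depth, m.
#' @param half_width Slab width above and below, m.
#' @param dz Centre-to-centre separation used as the shear denominator, m.
#' @return Complex vector (one value per time step), s^-1:
#'   \eqn{\partial u/\partial z + i \partial v/\partial z} with z upward
#'   through the thermocline (above-minus-below).
#' @export
shear_at_depth <- function(depths, u, v, z0, half_width = 10,
                           dz = half_width) {
  above <- depths >= z0 - half_width & depths <= z0
  below <- depths > z0 & depths <= z0 + half_width
  grid <- stats::median(diff(sort(unique(depths))))
  if (!any(above) || !any(below) ||
      min(depths) > z0 - half_width + grid ||
      max(depths) < z0 + half_width - grid)
    stop(sprintf("velocity profiles do not cover [%g, %g] m around z0 = %g",
                 z0 - half_width, z0 + half_width, z0))
  w <- u + 1i * v
  ua <- colMeans(w[above, , drop = FALSE])
  ub <- colMeans(w[below, , drop = FALSE])
  (ua - ub) / dz
}

#' Rotary spectra of a complex series on sliding windows
#'
#' Each 50%-overlapping window of length `window_days` is demeaned,
#' optionally Hann-tapered (with power re-normalisation by the taper's mean
#' square), Fourier transformed, and split into clockwise and
#' anticlockwise rotary components. With the Northern-hemisphere
#' convention used here, clockwise rotation of \eqn{u + iv} corresponds to
#' the negative frequencies of the complex series.
#'
#' Spectral values are variance per frequency bin, so with `taper =
#' "none"` the sum of the CW and ACW spectra equals the windowed series
#' variance exactly (Parseval).
#'
#' @param time Times (`POSIXct`), uniform cadence.
#' @param shear Complex series (e.g. from [shear_at_depth()]).
#' @param window_days Window length, days.
#' @param overlap Fractional overlap between consecutive windows.
#' @param taper `"hann"` (default) or `"none"`.
#' @param max_gap_frac Windows with more than this fraction of missing
#'   values are skipped.
#'
#' @return A list of class `"rotary_spectra"`; element `windows` is a list
#'   whose entries have `centre` (POSIXct), `freq_cpd` (positive grid,
#'   resolution 1/window), `cw`, `acw` (variance per bin, (s^-1)^2).
#' @export
rotary_spectrum <- function(time, shear, window_days = 3.5, overlap = 0.5,
                            taper = c("hann", "none"),
                            max_gap_frac = 0.10) {
  taper <- match.arg(taper)
  dt_days <- as.numeric(difftime(time[2], time[1], units = "days"))
  n_win <- round(window_days / dt_days)
  if (n_win > length(shear)) stop("series shorter than one window")
  step <- max(1L, round(n_win * (1 - overlap)))
  starts <- seq(1L, length(shear) - n_win + 1L, by = step)

  w_taper <- if (taper == "hann") {
    k <- seq_len(n_win) - 1L
    0.5 * (1 - cos(2 * pi * k / (n_win - 1)))
  } else rep(1, n_win)
  norm <- mean(w_taper^2)

  windows <- list()
  for (s in starts) {
    x <- shear[s:(s + n_win - 1L)]
    if (mean(!is.finite(x)) > max_gap_frac) next
    x[!is.finite(x)] <- 0 + 0i
    x <- x - mean(x)
    X <- stats::fft(x * w_taper)
    p <- Mod(X)^2 / n_win^2 / norm           # variance per bin
    # positive frequencies j = 1 .. floor((n-1)/2): ACW; their mirrors: CW
    jmax <- floor((n_win - 1) / 2)
    j <- seq_len(jmax)
    freq <- j / (n_win * dt_days)
    acw <- p[j + 1L]
    cw <- p[n_win + 1L - j]
    if (n_win %% 2 == 0) {          # Nyquist bin: unsigned; file under CW
      freq <- c(freq, (n_win / 2) / (n_win * dt_days))
      acw <- c(acw, 0)
      cw <- c(cw, p[n_win / 2 + 1L])
    }
    windows[[length(windows) + 1L]] <- list(
      centre = time[s] + (n_win - 1) / 2 * dt_days * 86400,
      freq_cpd = freq,
      acw = acw,
      cw = cw,
      var_window = sum(p[-1L]))
  }
  structure(list(windows = windows, window_days = n_win * dt_days,
                 taper = taper), class = "rotary_spectra")
}

#' Band definition for the tidal / inertial separation
#'
#' @param latitude Latitude, degrees (sets the inertial frequency).
#' @param tidal_periods_h Constituent periods averaged into the effective
#'   tidal period (default M2 and S2).
#' @param window_days Spectral window length, days.
#' @param overlap Window overlap fraction.
#' @return List with `inertial_period_h`, `inertial_cpd`,
#'   `tidal_period_h`, `tidal_cpd`, `window_days`, `overlap`,
#'   `rayleigh_ok`.
#' @export
band_definition <- function(latitude = 49.2,
                            tidal_periods_h = c(12.4206, 12.0000),
                            window_days = 3.5, overlap = 0.5) {
  inert <- inertial_frequency(latitude)
  tp <- effective_tidal_period(tidal_periods_h)
  list(inertial_period_h = inert$period_h,
       inertial_cpd = inert$cpd,
       tidal_period_h = tp,
       tidal_cpd = 24 / tp,
       window_days = window_days, overlap = overlap,
       rayleigh_ok = rayleigh_separable(window_days, inert$cpd, 24 / tp))
}

#' Extract band amplitudes (CW + ACW) from rotary spectra
#'
#' For each window, the spectral value at the grid frequency nearest each
#' target frequency is extracted and the clockwise and anticlockwise
#' contributions summed.
#'
#' @param spectra A `"rotary_spectra"` object.
#' @param band A [band_definition()].
#' @return Data frame `window_centre`, `inertial_amp`, `tidal_amp`
#'   ((s^-1)^2 spectral variance, CW + ACW).
#' @export
band_amplitude <- function(spectra, band = band_definition()) {
  rows <- lapply(spectra$windows, function(w) {
    pick <- function(target) {
      j <- which.min(abs(w$freq_cpd - target))
      w$cw[j] + w$acw[j]
    }
    data.frame(window_centre = w$centre,
               inertial_amp = pick(band$inertial_cpd),
               tidal_amp = pick(band$tidal_cpd))
  })
  do.call(rbind, rows)
}

#' Rayleigh criterion for frequency separation
#'
#' Two frequencies are separable in a record of length `window_days` iff
#' \eqn{|f_1 - f_2| \times T \ge 1}.
#'
#' @param window_days Record length, days.
#' @param f1,f2 Frequencies, cycles per day.
#' @return Logical.
#' @export
rayleigh_separable <- function(window_days, f1, f2) {
  abs(f1 - f2) * window_days >= 1
}

#' Local inertial frequency
#'
#' \eqn{f = 2 \Omega \sin(\phi)} with \eqn{\Omega = 7.2921\times10^{-5}}
#' rad s^-1.
#'
#' @param latitude Latitude, degrees (non-zero).
#' @return List `f_s` (rad s^-1), `period_h`, `cpd`.
#' @export
inertial_frequency <- function(latitude) {
  if (any(latitude == 0)) stop("inertial frequency undefined at the equator")
  omega <- 7.2921e-5
  f <- 2 * omega * sin(latitude * pi / 180)
  period_s <- 2 * pi / abs(f)
  list(f_s = f, period_h = period_s / 3600, cpd = 86400 / period_s)
}

#' Effective tidal period
#'
#' Arithmetic mean of constituent periods (e.g. M2 = 12.4206 h and
#' S2 = 12.0000 h give 12.21 h, i.e. 1.97 cpd).
#'
#' @param periods_h Constituent periods, hours.
#' @return Mean period, hours.
#' @export
effective_tidal_period <- function(periods_h = c(12.4206, 12.0000)) {
  if (!length(periods_h)) stop("at least one constituent period is required")
  mean(periods_h)
}

#' Wind and tide forcing proxies with threshold flags
#'
#' Computes the tidal-energy proxy \eqn{U^3} (24 h centred running mean of
#' the cubed current speed at the reference depth) and the wind-energy
#' proxy \eqn{W_s \tau_s} (wind speed times wind stress), and flags times
#' exceeding the conventional strong-forcing thresholds.
#'
#' @param time Times (`POSIXct`), uniform cadence.
#' @param u47 Current speed at the reference depth, m s^-1.
#' @param wind_speed Wind speed, m s^-1.
#' @param wind_stress Wind stress, Pa.
#' @param tide_threshold Strong-tide threshold on \eqn{U^3}, m^3 s^-3.
#' @param wind_threshold Strong-wind threshold on \eqn{W_s\tau_s}, W m^-2.
#' @return Data frame `time`, `u47_cubed`, `wind_power`, `tide_strong`,
#'   `wind_strong`.
#' @export
forcing_proxies <- function(time, u47, wind_speed, wind_stress,
                            tide_threshold = 0.06, wind_threshold = 3) {
  dt_h <- as.numeric(difftime(time[2], time[1], units = "hours"))
  u3_run <- running_mean(abs(u47)^3, 24 / dt_h)   # centred 24 h window
  wp <- wind_speed * wind_stress
  data.frame(time = time, u47_cubed = as.numeric(u3_run), wind_power = wp,
             tide_strong = as.numeric(u3_run) > tide_threshold,
             wind_strong = wp > wind_threshold)
}
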