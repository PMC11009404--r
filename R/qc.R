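#' Quality-control an ADCP burst
#'
#' Applies, in order: the phase-wrap velocity range screen, the correlation
#' screen, the across-beam echo-intensity ("fish") screen, and finally a
#' single 3-standard-deviation outlier pass computed per (beam, bin) over the
#' burst's samples after the preceding rules. No detrending is applied to the
#' cleaned data: the three-term structure-function regression absorbs linear
#' shear, so the mean profile is left in place.
#'
#' @param burst An [adcp_burst()].
#' @param config An [adcp_config()]; defaults to the burst's own config.
#' @param vmin,vmax Velocity acceptance range, m s^-1. Values outside
#'   `[vmin, vmax]` are taken to be phase-wrapped and rejected.
#' @param corr_threshold Minimum acceptable correlation count; values
#'   *below* the threshold are rejected (the threshold itself is kept).
#' @param fish_threshold Across-beam echo-intensity spread (counts) above
#'   which the offending beam's cell is rejected; see [fish_rejection()].
#' @param sd_mult Multiplier for the outlier pass (3 = classic 3-sigma).
#' @param sd_scope `"pooled"` (default) computes one mean/sd per (beam, bin)
#'   pooling the burst's samples; `"beam"` pools over the whole beam.
#'
#' @return The burst with `qc_mask` updated. An all-masked burst is returned
#'   (flagged unresolvable downstream), not an error.
#' @export
qc_burst <- function(burst, config = burst$config,
                     vmin = -1.1, vmax = 1.2,
                     corr_threshold = 75,
                     fish_threshold = 50,
                     sd_mult = 3,
                     sd_scope = c("pooled", "beam")) {
  sd_scope <- match.arg(sd_scope)
  d <- dim(burst$velocity)
  if (d[1] != config$n_beams || d[2] != config$n_bins ||
      d[3] != config$burst_samples)
    stop("burst dimensions do not match config")

  m <- burst$qc_mask
  m <- m | is.na(burst$velocity)
  m <- m | burst$velocity < vmin | burst$velocity > vmax
  m <- m | burst$correlation < corr_threshold
  m <- m | fish_rejection(burst$echo_intensity, fish_threshold)

  # 3-sd outlier pass on the surviving values, single (non-iterated) pass
  v <- burst$velocity
  v[m] <- NA_real_
  if (sd_scope == "pooled") {
    mu <- apply(v, c(1, 2), mean, na.rm = TRUE)
    sg <- apply(v, c(1, 2), stats::sd, na.rm = TRUE)
    mu_a <- array(mu, dim = d)   # recycles over the sample dimension
    sg_a <- array(sg, dim = d)
  } else {
    mu <- apply(v, 1, mean, na.rm = TRUE)
    sg <- apply(v, 1, stats::sd, na.rm = TRUE)
    mu_a <- array(mu, dim = d)
    sg_a <- array(sg, dim = d)
  }
  out <- !is.na(v) & !is.na(sg_a) & sg_a > 0 &
    abs(v - mu_a) > sd_mult * sg_a
  m <- m | out

  burst$qc_mask <- m
  burst
}

#' Across-beam echo-intensity (fish) screening
#'
#' Biological scatterers (fish) inflate the echo intensity of individual
#' beams. For each (bin, sample) cell the beam echo intensities are compared
#' with the minimum across beams; beams exceeding the minimum by more than
#' `threshold` counts are masked (manufacturer-style screening).
#'
#' @param echo_intensity Array `(beam, bin, sample)` of echo counts.
#' @param threshold Spread threshold in counts (default 50, the conventional
#'   manufacturer default).
#'
#' @return Logical array of the same shape, `TRUE` where rejected.
#' @export
fish_rejection <- function(echo_intensity, threshold = 50) {
  if (length(threshold) != 1 || !is.finite(threshold) || threshold <= 0)
    stop("fish-rejection threshold must be a single positive number")
  if (any(echo_intensity < 0, na.rm = TRUE))
    stop("echo intensity must be non-negative")
  lo <- apply(echo_intensity, c(2, 3), min, na.rm = TRUE)
  d <- dim(echo_intensity)
  lo_a <- aperm(array(lo, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  (echo_intensity - lo_a) > threshold
}
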