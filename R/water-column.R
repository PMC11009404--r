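#' Decompose a temperature profile into SML / thermocline / deep layers
#'
#' Stratification is first tested with the classic mixed-layer criterion:
#' if no depth is more than `delta_t` colder than the near-surface mean
#' (mean over the top `ref_depth` m) the profile is flagged as having no
#' thermocline. Otherwise the thermocline edges are located from the
#' temperature-gradient profile: the profile is smoothed with a running
#' mean of width `smooth_m` (gradients of raw 1 m CTD data are noise
#' dominated), and the thermocline top and bottom are the interpolated
#' depths at which the gradient magnitude crosses `grad_frac` of its peak.
#' With the default half-maximum crossing this is the classic FWHM edge
#' estimator, which locates the edges of a linear-gradient thermocline
#' without bias under symmetric smoothing. The SML base is identified with
#' the thermocline top.
#'
#' @param depth Depths, m, positive downward.
#' @param temperature Temperature profile, degrees C.
#' @param delta_t Stratification-existence criterion, degrees C below the
#'   near-surface mean.
#' @param ref_depth Depth over which the near-surface mean is taken, m.
#' @param grad_frac Fraction of the peak gradient at which the thermocline
#'   edges are placed (0.5 = full width at half maximum).
#' @param smooth_m Running-mean smoothing width, m.
#'
#' @return A list of class `"layer_decomposition"`: `sml_depth`,
#'   `thermocline_top`, `thermocline_bottom`, `thickness`, `deep_top`,
#'   `has_thermocline`. An unstratified profile returns
#'   `has_thermocline = FALSE` with `NA` bounds.
#' @export
identify_layers <- function(depth, temperature, delta_t = 0.5,
                            ref_depth = 5, grad_frac = 0.5, smooth_m = 7) {
  o <- order(depth)
  depth <- depth[o]; temperature <- temperature[o]
  surf <- mean(temperature[depth <= max(ref_depth, min(depth))])
  if (max(surf - temperature) < delta_t) {
    return(structure(list(sml_depth = NA_real_, thermocline_top = NA_real_,
                          thermocline_bottom = NA_real_, thickness = NA_real_,
                          deep_top = NA_real_, has_thermocline = FALSE),
                     class = "layer_decomposition"))
  }
  tsm <- running_mean(temperature, smooth_m / stats::median(diff(depth)))

  grad <- abs(diff(tsm) / diff(depth))
  mid <- (depth[-1] + depth[-length(depth)]) / 2
  imax <- which.max(grad)
  thr <- grad_frac * grad[imax]

  cross <- function(i0, i1) {
    # interpolated depth where grad crosses thr between adjacent points
    g0 <- grad[i0]; g1 <- grad[i1]
    if (g1 == g0) return(mid[i1])
    mid[i0] + (mid[i1] - mid[i0]) * (thr - g0) / (g1 - g0)
  }
  # scan outward from the gradient peak: robust to detached noise spikes
  it <- imax
  while (it > 1L && grad[it - 1L] >= thr) it <- it - 1L
  top <- if (it > 1L) cross(it - 1L, it) else mid[1]
  ib <- imax
  while (ib < length(grad) && grad[ib + 1L] >= thr) ib <- ib + 1L
  bottom <- if (ib < length(grad)) cross(ib + 1L, ib) else mid[length(mid)]

  structure(list(sml_depth = top, thermocline_top = top,
                 thermocline_bottom = bottom, thickness = bottom - top,
                 deep_top = bottom, has_thermocline = TRUE),
            class = "layer_decomposition")
}

#' @export
print.layer_decomposition <- function(x, ...) {
  if (!x$has_thermocline) {
    cat("<layer_decomposition> no thermocline (isothermal profile)\n")
  } else {
    cat(sprintf(
      "<layer_decomposition> SML %.1f m | thermocline %.1f-%.1f m (%.1f m thick) | deep below %.1f m\n",
      x$sml_depth, x$thermocline_top, x$thermocline_bottom, x$thickness,
      x$deep_top))
  }
  invisible(x)
}

#' Direct (local-fit) diapycnal gradient
#'
#' Least-squares slope of a scalar against depth over a window centred on
#' `centre_depth`. Intended for CTD profiles (10 m window) or discrete
#' bottle levels (window = thermocline extent); bottle values are used at
#' their native levels, never interpolated onto a finer grid.
#'
#' @param depth Depths, m, positive downward.
#' @param values Scalar values at `depth` (any per-metre-compatible units).
#' @param centre_depth Evaluation depth, m.
#' @param window Window full-width, m.
#' @param uncertainty_frac Fractional gradient uncertainty carried through
#'   to the flux budget (the conventional ~10%).
#'
#' @return A list of class `"gradient_estimate"`: `value` (units m^-1,
#'   positive = increasing downward), `method`, `depth`, `n`,
#'   `uncertainty_frac`.
#' @export
gradient_direct <- function(depth, values, centre_depth, window = 10,
                            uncertainty_frac = 0.10) {
  keep <- is.finite(depth) & is.finite(values)
  depth <- depth[keep]; values <- values[keep]
  sel <- abs(depth - centre_depth) <= window / 2
  if (sum(sel) < 3)
    stop("fewer than 3 points in the window; use gradient_bulk() instead")
  slope <- stats::cov(depth[sel], values[sel]) / stats::var(depth[sel])
  structure(list(value = slope, method = "direct", depth = centre_depth,
                 n = sum(sel), uncertainty_frac = uncertainty_frac),
            class = "gradient_estimate")
}

#' Bulk (two-layer) diapycnal gradient
#'
#' Difference between the deep-layer and SML mean values divided by the
#' thermocline thickness. With depth positive downward, a quantity larger
#' at depth has a positive gradient.
#'
#' @param sml_mean,deep_mean Layer-mean scalar values.
#' @param layers A `"layer_decomposition"` from [identify_layers()].
#' @param uncertainty_frac Fractional gradient uncertainty.
#' @return A `"gradient_estimate"` (see [gradient_direct()]).
#' @export
gradient_bulk <- function(sml_mean, deep_mean, layers,
                          uncertainty_frac = 0.10) {
  if (!isTRUE(layers$has_thermocline))
    stop("no thermocline identified; bulk gradient undefined")
  if (!is.finite(layers$thickness) || layers$thickness <= 0)
    stop("thermocline thickness must be positive")
  structure(list(value = (deep_mean - sml_mean) / layers$thickness,
                 method = "bulk",
                 depth = (layers$thermocline_top + layers$thermocline_bottom) / 2,
                 n = 2L, uncertainty_frac = uncertainty_frac),
            class = "gradient_estimate")
}

#' @export
print.gradient_estimate <- function(x, ...) {
  cat(sprintf("<gradient_estimate> %.4g per m (%s, at %.1f m, +/- %.0f%%)\n",
              x$value, x$method, x$depth, 100 * x$uncertainty_frac))
  invisible(x)
}

#' Centred running mean with shrinking end windows
#'
#' Boxcar running mean of width ~`n` points; at the series ends the
#' window shrinks symmetrically to the available points, so the output
#' never contains `NA` padding.
#'
#' @param x Numeric vector.
#' @param n Target window width, points (rounded; forced odd).
#' @return Smoothed vector, same length.
#' @keywords internal
running_mean <- function(x, n) {
  n <- max(1L, round(n))
  if (n %% 2 == 0) n <- n + 1L
  if (n == 1L) return(x)
  h <- (n - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(1L, i - h); hi <- pmin(length(x), i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Layer-mean value of a profile
#'
#' @param depth,values Profile.
#' @param zmin,zmax Depth band, m.
#' @return Mean of `values` for `zmin <= depth <= zmax`.
#' @export
layer_mean <- function(depth, values, zmin, zmax) {
  sel <- depth >= zmin & depth <= zmax & is.finite(values)
  if (!any(sel)) stop("no values in the requested layer")
  mean(values[sel])
}
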