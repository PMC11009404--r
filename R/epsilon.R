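#' Estimate dissipation from a single ADCP burst
#'
#' The central estimator of the package. Runs the full per-burst chain:
#' quality control ([qc_burst()]), structure function
#' ([structure_function()]), the three-term regression per (beam, bin)
#' ([fit_modified()]), coefficient screening ([screen_fit()]),
#' \eqn{\epsilon = (a_1/C_2)^{3/2}} per resolved bin, and the two-level
#' aggregation: arithmetic mean across the resolved bins of each beam
#' (subject to a minimum of `min_bins` resolved bins, default 6) and then
#' across the resolved beams.
#'
#' @param burst An [adcp_burst()].
#' @param config An [adcp_config()]; defaults to the burst's own.
#' @param qc Apply [qc_burst()] first (set `FALSE` if already masked).
#' @param min_bins Minimum resolved bins for a beam to contribute.
#' @param three_term Use the contamination-isolating three-term model
#'   (default). `FALSE` fits the plain two-term model, for bias studies.
#' @param ... Passed to [qc_burst()].
#'
#' @return An object of class `"epsilon_fit"`: a list with `epsilon`
#'   (burst-mean dissipation, W kg^-1, `NA` if unresolved), `valid`,
#'   `per_beam` (per-beam mean epsilon), `n_resolved` (resolved bins per
#'   beam), `fits` (data frame of per-(beam, bin) coefficients, screening
#'   reasons and bin epsilon), `timestamp` and `config`.
#' @seealso [daily_epsilon()] for day-level aggregation,
#'   [bursts_epsilon()] for a series of bursts.
#' @export
estimate_epsilon <- function(burst, config = burst$config, qc = TRUE,
                             min_bins = 6L, three_term = TRUE, ...) {
  if (qc) burst <- qc_burst(burst, config, ...)
  sf <- structure_function(burst, config)
  nmax <- config$n_beams * config$n_bins
  beam <- bin <- n_pts <- integer(nmax)
  a0 <- a1 <- a3 <- eps <- numeric(nmax)
  valid <- logical(nmax)
  reason <- character(nmax)
  nr <- 0L
  for (b in seq_along(sf)) {
    dllm <- sf[[b]]$dll
    for (i in seq_len(nrow(dllm))) {
      if (all(is.na(dllm[i, ]))) next
      fit <- fit_modified(sf[[b]]$separations, dllm[i, ],
                          three_term = three_term)
      scr <- screen_fit(fit)
      nr <- nr + 1L
      beam[nr] <- b; bin[nr] <- i
      a0[nr] <- fit$a0; a1[nr] <- fit$a1; a3[nr] <- fit$a3
      n_pts[nr] <- fit$n_points
      valid[nr] <- scr$valid; reason[nr] <- scr$reason
      eps[nr] <- if (scr$valid) epsilon_from_fit(fit$a1, config$c2)
                 else NA_real_
    }
  }
  idx <- seq_len(nr)
  fits <- data.frame(beam = beam[idx], bin = bin[idx], a0 = a0[idx],
                     a1 = a1[idx], a3 = a3[idx], n_points = n_pts[idx],
                     valid = valid[idx], reason = reason[idx],
                     epsilon = eps[idx])

  per_beam <- rep(NA_real_, config$n_beams)
  n_resolved <- integer(config$n_beams)
  for (b in seq_len(config$n_beams)) {
    e <- fits$epsilon[fits$beam == b & fits$valid]
    n_resolved[b] <- length(e)
    if (length(e) >= min_bins) per_beam[b] <- mean(e)
  }
  ok <- is.finite(per_beam)
  structure(list(
    epsilon = if (any(ok)) mean(per_beam[ok]) else NA_real_,
    valid = any(ok),
    per_beam = per_beam,
    n_resolved = n_resolved,
    fits = fits,
    timestamp = burst$timestamp,
    config = config
  ), class = "epsilon_fit")
}

#' @export
print.epsilon_fit <- function(x, ...) {
  cat("<epsilon_fit>", format(x$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"), "\n")
  if (x$valid)
    cat(sprintf("  burst-mean epsilon: %.3g W kg^-1 (%d/%d beams resolved)\n",
                x$epsilon, sum(is.finite(x$per_beam)), length(x$per_beam)))
  else cat("  burst unresolved\n")
  invisible(x)
}

#' @export
summary.epsilon_fit <- function(object, ...) {
  cat("Structure-function dissipation estimate\n")
  print(object)
  cat(sprintf("  resolved bins per beam: %s\n",
              paste(object$n_resolved, collapse = ", ")))
  tab <- table(object$fits$reason)
  cat("  screening outcomes:\n")
  for (nm in names(tab)) cat(sprintf("    %-18s %d\n", nm, tab[[nm]]))
  invisible(object)
}

#' @export
coef.epsilon_fit <- function(object, ...) {
  object$fits[, c("beam", "bin", "a0", "a1", "a3", "valid")]
}

#' Plot per-bin dissipation estimates of a burst
#'
#' Shows the screened per-bin epsilon values by beam and bin, with the
#' burst mean overlaid; a quick visual check of vertical structure and of
#' how many bins survived screening.
#'
#' @param x An `"epsilon_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epsilon_fit <- function(x, ...) {
  f <- x$fits[x$fits$valid, ]
  if (!nrow(f)) {
    warning("no valid fits to plot")
    return(invisible(x))
  }
  graphics::plot(f$epsilon, f$bin, log = "x", col = f$beam, pch = 16,
                 xlab = expression(epsilon ~ (W ~ kg^-1)), ylab = "bin",
                 ylim = rev(range(f$bin)),
                 main = format(x$timestamp, "%Y-%m-%d %H:%M"), ...)
  if (x$valid) graphics::abline(v = x$epsilon, lty = 2)
  graphics::legend("topright", legend = paste("beam", unique(f$beam)),
                   col = unique(f$beam), pch = 16, bty = "n")
  invisible(x)
}

#' Burst-mean dissipation from screened per-bin values
#'
#' Aggregates per-bin epsilon values for one burst: arithmetic mean across
#' the resolved bins of each beam (beams with fewer than `min_bins`
#' resolved bins are dropped), then arithmetic mean across surviving beams.
#'
#' @param eps_by_beam List (one element per beam) of numeric vectors of
#'   resolved per-bin epsilon values.
#' @param min_bins Minimum resolved bins per contributing beam.
#' @return List `(epsilon, per_beam, n_resolved, valid)`.
#' @export
burst_mean_epsilon <- function(eps_by_beam, min_bins = 6L) {
  per_beam <- vapply(eps_by_beam, function(e) {
    e <- e[is.finite(e)]
    if (length(e) >= min_bins) mean(e) else NA_real_
  }, numeric(1))
  ok <- is.finite(per_beam)
  list(epsilon = if (any(ok)) mean(per_beam[ok]) else NA_real_,
       per_beam = per_beam,
       n_resolved = vapply(eps_by_beam, function(e) sum(is.finite(e)),
                           integer(1)),
       valid = any(ok))
}

#' Estimate dissipation for a series of bursts
#'
#' @param bursts List of [adcp_burst()] objects.
#' @param ... Passed to [estimate_epsilon()].
#' @return Data frame with `timestamp`, `epsilon`, `valid`.
#' @export
bursts_epsilon <- function(bursts, ...) {
  res <- lapply(bursts, estimate_epsilon, ...)
  data.frame(
    timestamp = as.POSIXct(vapply(res, function(r)
      as.numeric(r$timestamp), numeric(1)), origin = "1970-01-01", tz = "UTC"),
    epsilon = vapply(res, function(r) r$epsilon, numeric(1)),
    valid = vapply(res, function(r) r$valid, logical(1)))
}

#' Daily-mean dissipation
#'
#' Arithmetic mean of the resolved burst values within each UTC calendar
#' day. A day is valid only when at least `min_frac` of the potential
#' `bursts_per_day` bursts are resolved (default 75% of 72 = 54). The
#' multiplicative sub-daily spread (max/min of resolved burst values) is
#' recorded, together with the fractional standard error of the daily mean,
#' which feeds the flux uncertainty budget.
#'
#' @param burst_series Data frame from [bursts_epsilon()] (columns
#'   `timestamp`, `epsilon`, `valid`).
#' @param bursts_per_day Potential bursts per day (3/hour x 24 h = 72).
#' @param min_frac Minimum resolved fraction for a valid day.
#'
#' @return Data frame with one row per day: `date`, `epsilon_daily`,
#'   `n_bursts_resolved`, `valid`, `sub_daily_spread`, `se_frac`.
#' @export
daily_epsilon <- function(burst_series, bursts_per_day = 72L,
                          min_frac = 0.75) {
  day <- as.Date(burst_series$timestamp, tz = "UTC")
  out <- lapply(split(burst_series, day), function(g) {
    e <- g$epsilon[g$valid & is.finite(g$epsilon)]
    n <- length(e)
    data.frame(
      date = as.Date(g$timestamp[1], tz = "UTC"),
      epsilon_daily = if (n) mean(e) else NA_real_,
      n_bursts_resolved = n,
      valid = n >= ceiling(min_frac * bursts_per_day),
      sub_daily_spread = if (n && min(e) > 0) max(e) / min(e) else NA_real_,
      se_frac = if (n > 1 && mean(e) > 0)
        stats::sd(e) / sqrt(n) / mean(e) else 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
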