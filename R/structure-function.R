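#' Second-order structure function of an ADCP burst
#'
#' Computes \eqn{D_{LL}(z_i, r)}, the mean over unmasked samples of the
#' squared along-beam velocity difference at separation \eqn{r}, using a
#' bin-centred difference scheme: for bin centre \eqn{i} and half-step
#' \eqn{k}, the difference is \eqn{\nu(z_{i+k}) - \nu(z_{i-k})} so that
#' separations advance in steps of `separation_step * bin_size`
#' (0.2 m with the defaults). The cleaned velocity is used directly - no
#' mean or trend removal - because the three-term regression of
#' [fit_modified()] isolates shear and wave contamination instead.
#'
#' Pairs in which either cell is masked are dropped from the mean; a
#' (bin, r) combination with fewer than `min_pairs` unmasked sample pairs is
#' omitted (returned as `NA`).
#'
#' @param burst A QC-masked [adcp_burst()] (see [qc_burst()]).
#' @param config An [adcp_config()]; defaults to the burst's own.
#' @param min_pairs Minimum unmasked sample pairs per (bin, r) cell.
#'
#' @return A list with one element per beam, each a list with
#'   `separations` (vector of r, m), `dll` (matrix bin x r, m^2 s^-2, `NA`
#'   where unavailable) and `n_pairs` (matrix of contributing pair counts).
#' @export
structure_function <- function(burst, config = burst$config, min_pairs = 2L) {
  nb <- config$n_bins
  step <- config$separation_step
  kmax <- config$rmax_bins
  seps <- (seq_len(kmax) * step) * config$bin_size
  if (step %% 2 != 0)
    stop("separation_step must be even so pair centres fall on a bin")

  v <- burst$velocity
  v[burst$qc_mask] <- NA_real_

  lapply(seq_len(config$n_beams), function(b) {
    V <- v[b, , , drop = TRUE]          # bins x samples
    dll <- matrix(NA_real_, nb, kmax)
    npairs <- matrix(0L, nb, kmax)
    for (k in seq_len(kmax)) {
      off <- k * step                   # full bin offset between the pair
      if (off >= nb) break
      lo <- seq_len(nb - off)           # lower bin of each centred pair
      hi <- lo + off
      centres <- lo + off / 2
      dv2 <- (V[hi, , drop = FALSE] - V[lo, , drop = FALSE])^2
      n <- rowSums(!is.na(dv2))
      m <- rowMeans(dv2, na.rm = TRUE)
      m[n < min_pairs] <- NA_real_
      dll[centres, k] <- m
      npairs[centres, k] <- n
    }
    list(separations = seps, dll = dll, n_pairs = npairs)
  })
}

#' Three-term structure-function regression
#'
#' Least-squares fit of \eqn{D_{LL}} against \eqn{x = r^{2/3}} with basis
#' \eqn{\{1, x, x^3\}}:
#' \deqn{D_{LL}(r) = a_0 + a_1 r^{2/3} + a_3 (r^{2/3})^3}
#' Since \eqn{(r^{2/3})^3 = r^2}, the cubic term absorbs non-turbulent
#' velocity differences that vary linearly with separation (surface waves,
#' instrument motion in a sheared flow, and steady shear), while \eqn{a_1}
#' carries the Kolmogorov \eqn{r^{2/3}} turbulent signal and \eqn{a_0}
#' the uncorrelated noise offset (2 x noise variance).
#'
#' @param separations Separation distances r, m (strictly increasing).
#' @param dll \eqn{D_{LL}} values, m^2 s^-2, same length (`NA` allowed;
#'   dropped).
#' @param three_term If `FALSE`, fit the plain two-term model
#'   \eqn{a_0 + a_1 r^{2/3}} (for bias comparisons); `a3` is then `NA`.
#'
#' @return A list `(a0, a1, a3, n_points, ok)`; `ok = FALSE` flags a
#'   rank-deficient or under-determined fit.
#' @export
fit_modified <- function(separations, dll, three_term = TRUE) {
  keep <- is.finite(separations) & is.finite(dll)
  r <- separations[keep]; y <- dll[keep]
  n <- length(r)
  p <- if (three_term) 3L else 2L
  if (n < p)
    return(list(a0 = NA_real_, a1 = NA_real_, a3 = NA_real_,
                n_points = n, ok = FALSE))
  x <- r^(2 / 3)
  X <- if (three_term) cbind(1, x, x^3) else cbind(1, x)
  qr_x <- qr(X)
  if (qr_x$rank < p)
    return(list(a0 = NA_real_, a1 = NA_real_, a3 = NA_real_,
                n_points = n, ok = FALSE))
  cf <- unname(qr.coef(qr_x, y))
  list(a0 = cf[1], a1 = cf[2],
       a3 = if (three_term) cf[3] else NA_real_,
       n_points = n, ok = TRUE)
}

#' Screen a structure-function fit
#'
#' A fit is retained only when all of the following hold:
#' \itemize{
#'   \item \eqn{a_3 \ge 0} (a negative contamination term is unphysical);
#'   \item \eqn{-10^{-4} \le a_0 \le 3 \times 10^{-4}} m^2 s^-2 (bounds
#'     inclusive: the rejection inequalities are strict);
#'   \item at least `min_points` (default 8) regression points;
#'   \item \eqn{a_1 \ge 0}, since \eqn{\epsilon = (a_1/C_2)^{3/2}} is not
#'     real otherwise.
#' }
#'
#' @param fit A fit list from [fit_modified()].
#' @param a0_min,a0_max Inclusive bounds on the offset, m^2 s^-2.
#' @param min_points Minimum number of regression points.
#'
#' @return A list `(valid, reason)`; `reason` is `"ok"` or the first rule
#'   that fired.
#' @export
screen_fit <- function(fit, a0_min = -1e-4, a0_max = 3e-4, min_points = 8L) {
  if (!isTRUE(fit$ok))
    return(list(valid = FALSE, reason = "fit failed"))
  if (fit$n_points < min_points)
    return(list(valid = FALSE, reason = "too few points"))
  if (is.finite(fit$a3) && fit$a3 < 0)
    return(list(valid = FALSE, reason = "a3<0"))
  if (fit$a0 < a0_min || fit$a0 > a0_max)
    return(list(valid = FALSE, reason = "a0 out of bounds"))
  if (fit$a1 < 0)
    return(list(valid = FALSE, reason = "a1<0"))
  list(valid = TRUE, reason = "ok")
}

#' Dissipation rate from a fitted structure-function slope
#'
#' \deqn{\epsilon = (a_1 / C_2)^{3/2}}
#'
#' @param a1 Fitted \eqn{r^{2/3}} coefficient, m^(4/3) s^-2 (must be >= 0;
#'   screened fits guarantee this).
#' @param c2 Empirical constant \eqn{C_2}.
#' @return Dissipation rate, W kg^-1.
#' @export
epsilon_from_fit <- function(a1, c2 = 2.1) {
  stopifnot(c2 > 0)
  if (any(a1 < 0, na.rm = TRUE))
    stop("a1 < 0: epsilon undefined; fits must be screened first")
  (a1 / c2)^(3 / 2)
}
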