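#' Dissipation flux coefficient from the flux Richardson number
#'
#' \deqn{\Gamma = R_f / (R_f + 1)}
#'
#' @param rf Flux Richardson number (> -1).
#' @return Dimensionless flux coefficient.
#' @export
gamma_from_rf <- function(rf) {
  if (any(rf == -1)) stop("Gamma undefined at rf = -1")
  rf / (rf + 1)
}

#' Diapycnal diffusivity by the dissipation (Osborn) method
#'
#' \deqn{K_z = \Gamma \, \epsilon / N^2}
#'
#' @param epsilon Dissipation rate, W kg^-1 (a number, or a row of
#'   [daily_epsilon()] output via its `epsilon_daily` column).
#' @param n2 Buoyancy frequency squared, s^-2 (must be > 0: the flux is
#'   undefined in unstable stratification).
#' @param gamma Dissipation flux coefficient (default 0.2).
#' @return An object of class `"kz_estimate"`: `value` (m^2 s^-1),
#'   `epsilon_used`, `n2_used`, `gamma`.
#' @export
kz_dissipation <- function(epsilon, n2, gamma = 0.2) {
  if (any(!is.finite(n2)) || any(n2 <= 0))
    stop("N^2 must be positive: diffusivity undefined in unstable stratification")
  if (any(!is.finite(epsilon)) || any(epsilon < 0))
    stop("epsilon must be finite and non-negative")
  structure(list(value = gamma * epsilon / n2,
                 epsilon_used = epsilon, n2_used = n2, gamma = gamma),
            class = "kz_estimate")
}

#' @export
print.kz_estimate <- function(x, ...) {
  cat(sprintf("<kz_estimate> K_z = %.3g m^2 s^-1 (eps %.3g W kg^-1, N^2 %.3g s^-2, Gamma %.2g)\n",
              x$value, x$epsilon_used, x$n2_used, x$gamma))
  invisible(x)
}

#' Diapycnal scalar flux
#'
#' \deqn{J = -K_z \, \partial C / \partial z}
#' Depth is positive downward throughout, so a scalar increasing downward
#' (positive gradient) gives a negative J: transport is upward. Stored
#' fluxes are signed with **positive = downward**; `direction` makes the
#' sense explicit. Output is converted from mmol m^-2 s^-1 to
#' mmol m^-2 d^-1 (x 86400).
#'
#' @param kz A `"kz_estimate"` (or bare diffusivity, m^2 s^-1).
#' @param gradient A `"gradient_estimate"` (or bare per-metre gradient in
#'   mmol m^-4; convert DIC umol kg^-1 m^-1 with [dic_to_volumetric()]).
#' @param quantity Label for reporting.
#' @param eps_se_frac Fractional standard error of the daily-mean epsilon
#'   (sub-daily variability), the dominant uncertainty term.
#' @param gamma_frac,grad_frac Fractional uncertainties of Gamma and of the
#'   gradient, combined in quadrature by [flux_uncertainty()].
#'
#' @return An object of class `"flux_estimate"`: `value` (signed,
#'   positive = downward, mmol m^-2 d^-1), `magnitude`, `direction`
#'   (`"up"`/`"down"`/`"none"`), `uncertainty`, `quantity`, `kz`,
#'   `gradient`.
#' @export
scalar_flux <- function(kz, gradient, quantity = "scalar",
                        eps_se_frac = 0, gamma_frac = 0.20,
                        grad_frac = NULL) {
  kz_val <- if (inherits(kz, "kz_estimate")) kz$value else kz
  g_val <- if (inherits(gradient, "gradient_estimate")) gradient$value else gradient
  if (is.null(grad_frac))
    grad_frac <- if (inherits(gradient, "gradient_estimate"))
      gradient$uncertainty_frac else 0.10
  if (!is.finite(g_val)) stop("gradient is missing")
  j <- -kz_val * g_val * 86400
  unc <- flux_uncertainty(j, eps_se_frac, gamma_frac, grad_frac)
  structure(list(value = j, magnitude = abs(j),
                 direction = if (j > 0) "down" else if (j < 0) "up" else "none",
                 uncertainty = unc, quantity = quantity,
                 kz = kz, gradient = gradient),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("<flux_estimate> %s: %.3g +/- %.2g mmol m^-2 d^-1 (%sward)\n",
              x$quantity, x$value, x$uncertainty, x$direction))
  invisible(x)
}

#' Diapycnal heat flux
#'
#' \deqn{J_{heat} = \rho_0 c_p K_z \, |\partial T/\partial z|}
#' reported positive in the down-gradient direction (warm SML to cool deep
#' water).
#'
#' @param kz A `"kz_estimate"` or bare diffusivity, m^2 s^-1.
#' @param dTdz Temperature gradient magnitude, K m^-1.
#' @param rho0 Reference density, kg m^-3.
#' @param cp Specific heat capacity of seawater, J kg^-1 K^-1.
#' @return Heat flux, W m^-2.
#' @export
heat_flux <- function(kz, dTdz, rho0 = 1025, cp = 3985) {
  kz_val <- if (inherits(kz, "kz_estimate")) kz$value else kz
  rho0 * cp * kz_val * abs(dTdz)
}

#' Flux uncertainty by quadrature
#'
#' The three uncertainty sources - sub-daily variability of epsilon
#' (expressed as the fractional standard error of the daily mean),
#' variability in Gamma (typically 20%) and the gradient estimate
#' (typically ~10%) - are treated as independent fractional errors and
#' combined in quadrature:
#' \deqn{\sigma_J = |J| \sqrt{f_\epsilon^2 + f_\Gamma^2 + f_{grad}^2}}
#'
#' @param flux Flux value (any units; the result has the same units).
#' @param eps_se_frac Fractional standard error from sub-daily epsilon
#'   variability.
#' @param gamma_frac Fractional Gamma uncertainty.
#' @param grad_frac Fractional gradient uncertainty.
#' @return Uncertainty, same units as `flux`.
#' @export
flux_uncertainty <- function(flux, eps_se_frac = 0, gamma_frac = 0.20,
                             grad_frac = 0.10) {
  abs(flux) * sqrt(eps_se_frac^2 + gamma_frac^2 + grad_frac^2)
}

#' Convert a DIC gradient from gravimetric to volumetric units
#'
#' @param grad_umol_kg_m DIC gradient, umol kg^-1 m^-1.
#' @param rho0 Reference density, kg m^-3.
#' @return Gradient in mmol m^-4.
#' @export
dic_to_volumetric <- function(grad_umol_kg_m, rho0 = 1025) {
  grad_umol_kg_m * rho0 / 1000
}

#' Carbon-to-nitrogen ratio of the diapycnal flux
#'
#' \eqn{|J_{DIC}| / |J_{NOx}|}. Because \eqn{K_z} cancels between two
#' fluxes sharing the same dissipation estimate, this equals the gradient
#' ratio, so epsilon uncertainty does not contribute; the quoted
#' uncertainty combines the two gradient fractions in quadrature.
#'
#' @param j_dic,j_nox `"flux_estimate"` objects (or bare flux values) for
#'   DIC and NOx on the same date.
#' @param grad_frac_dic,grad_frac_nox Fractional gradient uncertainties
#'   (used when bare values are supplied).
#' @return List `(ratio, uncertainty)`.
#' @export
cn_ratio <- function(j_dic, j_nox, grad_frac_dic = 0.10,
                     grad_frac_nox = 0.10) {
  v_dic <- if (inherits(j_dic, "flux_estimate")) j_dic$magnitude else abs(j_dic)
  v_nox <- if (inherits(j_nox, "flux_estimate")) j_nox$magnitude else abs(j_nox)
  if (inherits(j_dic, "flux_estimate") &&
      inherits(j_dic$gradient, "gradient_estimate"))
    grad_frac_dic <- j_dic$gradient$uncertainty_frac
  if (inherits(j_nox, "flux_estimate") &&
      inherits(j_nox$gradient, "gradient_estimate"))
    grad_frac_nox <- j_nox$gradient$uncertainty_frac
  if (v_nox == 0) stop("C:N ratio undefined for zero NOx flux")
  ratio <- v_dic / v_nox
  list(ratio = ratio,
       uncertainty = ratio * sqrt(grad_frac_dic^2 + grad_frac_nox^2))
}

#' Deep-water oxygen budget
#'
#' Diagnostic arithmetic linking the observed deep-water O2 decline to the
#' diapycnal fluxes out of the mid-water O2 maximum:
#' \itemize{
#'   \item `decline_rate` = (o2_start - o2_end) / interval, mmol m^-3 d^-1;
#'   \item `removal_flux` = decline_rate x layer_depth (the apparent O2
#'     removal, mmol m^-2 d^-1), plus `removal_flux_with_supply`, which
#'     adds the mean downward diapycnal supply back so that the figure
#'     represents gross consumption;
#'   \item per date: `total_out_of_max` = |up| + |down|,
#'     `fraction_upward` = 100 |up| / total;
#'   \item `counterfactual_decline` = removal_flux + |down| per date: the
#'     decline that would occur with no diapycnal O2 supply.
#' }
#'
#' @param fluxes A list with one element per date, each a list with
#'   elements `up` and `down`: O2 `"flux_estimate"`s (or bare signed
#'   values, positive = downward).
#' @param o2_start,o2_end Deep-water O2 at the two profile dates,
#'   mmol m^-3.
#' @param interval_days Days between the profiles.
#' @param layer_depth Deep-water layer depth, m.
#'
#' @return An object of class `"o2_budget"` (a list of the fields above).
#' @export
o2_budget <- function(fluxes, o2_start, o2_end, interval_days,
                      layer_depth = 100) {
  if (interval_days <= 0) stop("interval must be positive")
  mag <- function(f) if (inherits(f, "flux_estimate")) f$magnitude else abs(f)
  up <- vapply(fluxes, function(d) mag(d$up), numeric(1))
  down <- vapply(fluxes, function(d) mag(d$down), numeric(1))
  decline_rate <- (o2_start - o2_end) / interval_days
  removal <- decline_rate * layer_depth
  total <- up + down
  structure(list(
    o2_start = o2_start, o2_end = o2_end, interval = interval_days,
    layer_depth = layer_depth,
    decline_rate = decline_rate,
    removal_flux = removal,
    removal_flux_with_supply = removal + mean(down),
    total_out_of_max = total,
    fraction_upward = 100 * up / total,
    fraction_downward = 100 * down / total,
    counterfactual_decline = removal + down
  ), class = "o2_budget")
}

#' @export
print.o2_budget <- function(x, ...) {
  cat("<o2_budget>\n")
  cat(sprintf("  deep O2 %.1f -> %.1f mmol m^-3 over %g d: decline %.3f mmol m^-3 d^-1\n",
              x$o2_start, x$o2_end, x$interval, x$decline_rate))
  cat(sprintf("  apparent removal flux (%g m layer): %.1f mmol m^-2 d^-1 (%.1f incl. diapycnal supply)\n",
              x$layer_depth, x$removal_flux, x$removal_flux_with_supply))
  for (i in seq_along(x$total_out_of_max))
    cat(sprintf("  date %d: total out of O2 max %.1f mmol m^-2 d^-1, %.0f%% upward\n",
                i, x$total_out_of_max[i], x$fraction_upward[i]))
  cat(sprintf("  counterfactual decline without mixing: %.1f - %.1f mmol m^-2 d^-1\n",
              min(x$counterfactual_decline), max(x$counterfactual_decline)))
  invisible(x)
}

#' Format fluxes as a report table
#'
#' Produces a table shaped like a two-date flux summary: one row per
#' (date, quantity), with upward fluxes printed positive and downward
#' fluxes negative (display convention; internally positive = downward).
#'
#' @param rows A list of lists, each with `date`, `label`, `eps_depth` and
#'   `flux` (a `"flux_estimate"`).
#' @return Data frame with columns `date`, `name`, `eps_depth_m`,
#'   `flux_mmol_m2_d` (display sign), `uncertainty`.
#' @export
flux_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    disp <- -r$flux$value   # upward (internally negative) printed positive
    data.frame(date = r$date, name = r$label, eps_depth_m = r$eps_depth,
               flux_mmol_m2_d = disp, uncertainty = r$flux$uncertainty)
  }))
}
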