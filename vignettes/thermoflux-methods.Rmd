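---
title: "Methods: from ADCP bursts to a deep-water oxygen budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ADCP bursts to a deep-water oxygen budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoflux)
```

`thermoflux` estimates diapycnal mixing and the fluxes it drives across
a seasonal thermocline. This vignette documents the models, the
assumptions behind them, the tunable parameters, and the design choices
made where the methodology left the design genuinely open. It also
documents — candidly — the statistical behaviour of the screened
dissipation estimator, because it matters for interpreting validation
results.

## 1. Dissipation from the second-order structure function

A pulse-coherent ADCP measures along-beam velocity at 0.1 m resolution,
1 Hz, in 5-minute bursts (300 profiles) three times an hour. In the
inertial subrange of isotropic turbulence the second-order structure
function of the turbulent velocity obeys the Kolmogorov scaling

$$D_{LL}(z, r) \;=\; \langle [\nu'(z + r) - \nu'(z)]^2 \rangle
  \;=\; C_2\,\epsilon^{2/3} r^{2/3},$$

with $C_2$ an empirical constant. Surface waves, or the instrument
heading rocking in a sheared flow, superimpose velocity differences that
grow *linearly* with separation and therefore contribute an $r^2$ term
to $D_{LL}$. The package fits the three-term model

$$D_{LL}(z, r) = a_0 + a_1 r^{2/3} + a_3\,(r^{2/3})^3,$$

in which $(r^{2/3})^3 = r^2$: $a_1$ carries the turbulent signal
($\epsilon = (a_1/C_2)^{3/2}$), $a_3$ absorbs the wave/shear
contamination, and $a_0$ absorbs uncorrelated instrument noise (its
expectation is twice the noise variance). Because the $r^2$ term also
absorbs steady shear, no detrending is applied to the cleaned
velocities.

**Quality control** (in order): velocities outside $[-1.1, 1.2]$ m s⁻¹
are treated as phase-wrapped and rejected (wrapped values are rejected,
never "repaired"); correlations below 75 counts are rejected (75 itself
is kept); cells whose echo intensity exceeds the across-beam minimum by
more than 50 counts are rejected (fish screening — 50 counts is the
conventional manufacturer default, configurable); finally a single,
non-iterated 3-standard-deviation outlier pass is applied per (beam,
bin) over the burst's samples. The outlier pass pools each bin's
samples by default; a `sd_scope = "beam"` switch pools the whole beam
profile instead, since either reading of "over the burst and the beam
profile" is defensible.

**The difference scheme.** $D_{LL}$ uses bin-centred differences
$\nu(z_{i+k}) - \nu(z_{i-k})$, so separations advance in steps of two
bins ($r = 0.2, 0.4, \dots$ m). Sample pairs with either cell masked
are dropped; a (bin, $r$) cell needs at least 2 surviving pairs.

**Separation range.** The maximum half-step defaults to
`rmax_bins = 15`, i.e. $r$ up to 3.0 m — essentially the instrument's
~3.5 m profiling range. This matters: the regression basis
$\{1, x, x^3\}$ with $x = r^{2/3}$ is strongly collinear on a short
range (on $r \le 1.6$ m the fitted $a_1$ and $a_3$ have correlation
$\approx -0.95$), and extending the range is the single most effective
way to condition the fit. For real data with a limited inertial
subrange the range is configurable.

**Screening.** A fit is kept only if $a_3 \ge 0$,
$-10^{-4} \le a_0 \le 3\times10^{-4}$ m² s⁻² (bounds inclusive — the
rejection inequalities are strict), and at least 8 regression points
were available. Fits with $a_1 < 0$ are additionally rejected because
$(a_1/C_2)^{3/2}$ is not real; this case is not covered by the other
rules but cannot yield a dissipation estimate.

**Aggregation.** Per-bin $\epsilon$ values are averaged arithmetically
across the resolved bins of each beam (a beam needs at least 6), then
across beams to give the burst value, then across resolved bursts to
give a daily mean — valid only when at least 75% of the 72 potential
bursts of a UTC calendar day resolved. The multiplicative sub-daily
spread and the fractional standard error of the daily mean are recorded
for the uncertainty budget.

**Choice of $C_2$.** The constant is not fixed by the method itself; the
package adopts the conventional longitudinal-structure-function value
$C_2 = 2.1$, exposed in `adcp_config()`. All validation uses
prescribed-truth recovery, so the choice is visible rather than hidden.

### Known small-sample biases of the screened estimator

With 300 samples per burst the per-bin $\hat a_1$ is noisy (the
relative sampling error of each $D_{LL}$ point is
$\sqrt{2/300} \approx 8\%$, inflated by the basis collinearity), and
the estimator is nonlinear in $\hat a_1$. Two consequences, verified by
the seeded experiments in the test suite and `scripts/acceptance.R`:

* **Clean data are biased low.** When the true $a_3$ is zero (no
  contamination), the $a_3 \ge 0$ screen keeps roughly half the fits
  and — through the strong negative $\hat a_1$/$\hat a_3$ correlation —
  preferentially keeps low-$a_1$ fits. The ensemble-median recovered
  $\epsilon$ is then ~0.6–0.75 of the prescribed value across
  $\epsilon \in [10^{-8}, 10^{-6}]$ W kg⁻¹. The chain itself is
  unbiased: computing $\epsilon$ from the *unscreened* mean $a_1$
  recovers the truth to within a few percent (a property pinned in the
  tests).
* **Contaminated data are biased slightly high.** With genuine
  contamination the $a_3$ screen is essentially inactive, and the
  residual bias comes from the $a_1 \ge 0$ truncation plus the
  convexity of $a_1^{3/2}$ (Jensen), ~+20% at
  $\epsilon = 10^{-7}$ W kg⁻¹ and shrinking as the signal-to-noise
  ratio improves. For comparison, the *two-term* fit
  ($a_0 + a_1 r^{2/3}$) overestimates $\epsilon$ by a factor of several
  under the same contamination — the three-term model removes the
  first-order problem and leaves these second-order effects.

These are properties of the screening rules at this burst size, not of
the implementation; field deployments always carry some contamination,
which is the regime the screening rules were designed for. The
validation experiments therefore quote both regimes explicitly instead
of hiding the effect, and downstream closure checks inherit a
corresponding share of this bias at the lowest dissipation levels.

## 2. Stratification, layers and gradients

Density uses the international one-atmosphere equation of state for
seawater (quintic in $T$, with the $S$, $S^{3/2}$, $S^2$ salinity
terms); its published check values are pinned in the tests. Over the
scenario range ($T \in [5, 25]$ °C, $S \in [34, 36]$) it is accurate to
well under $10^{-2}$ kg m⁻³, ample for thermocline $N^2$. The buoyancy
frequency is $N^2 = (g/\rho_0)\,\partial\rho/\partial z$ with depth
positive downward and centred differences on the native grid;
inversions are returned negative with a stability flag, never clipped.

**Layer decomposition.** Stratification existence is tested with the
classic mixed-layer criterion (any depth more than 0.5 °C colder than
the near-surface mean). The thermocline edges are then located on the
temperature-gradient profile: the profile is smoothed with a ~7 m
running mean (with shrinking windows at the ends), and the edges are
the interpolated crossings of half the peak gradient, scanning outward
from the peak. Two deliberate choices here:

* *Half-maximum edges rather than a 10%-of-peak rule.* With 0.05 °C
  noise on a 1 m grid, raw adjacent-point gradients have a noise floor
  of ~30% of a typical thermocline peak gradient, so a low threshold on
  unsmoothed data latches onto noise far below the thermocline. The
  FWHM crossing on a symmetrically smoothed profile is unbiased for a
  linear-gradient thermocline, and scanning outward from the peak makes
  it robust to detached spikes.
* *SML base = thermocline top.* An offset criterion ("0.5 °C below the
  surface") sits systematically deeper than the physical top of the
  gradient region by (offset)/(gradient) — about 3 m for June-like
  conditions — which would violate the ordering SML ≤ top and bias the
  above-maximum oxygen gradient by ~15–20%. The gradient edge is used
  for both.

**Gradients** come in two flavours, as in standard practice: a *direct*
local least-squares slope over a window (default 10 m for CTD data;
bottle data are used at their native 12–14 levels, never interpolated
onto a finer grid), and a *bulk* two-layer estimate
(deep mean − SML mean)/thickness. On a profile linear inside the
thermocline and constant outside the two agree exactly; both carry a
~10% fractional uncertainty into the flux budget. Oxygen, whose profile
has an interior maximum, gets two-point gradients from the SML mean to
the maximum and from the maximum to the deep mean; the maximum is
located on a ~7 m smoothed profile because the flank gradients divide
by distances of order 15 m and raw 1 mmol m⁻³ noise would jitter the
maximum's position by several metres.

## 3. Fluxes, uncertainty and the oxygen budget

The dissipation (Osborn) method converts $\epsilon$ and $N^2$ into a
diapycnal diffusivity $K_z = \Gamma\,\epsilon/N^2$ with
$\Gamma = R_f/(R_f + 1)$ taken as 0.2. Scalar fluxes are
$J = -K_z\,\partial C/\partial z$, converted to mmol m⁻² d⁻¹; heat flux
is $\rho_0 c_p K_z\,|\partial T/\partial z|$ with $\rho_0 = 1025$ kg
m⁻³ and $c_p = 3985$ J kg⁻¹ K⁻¹. DIC gradients in µmol kg⁻¹ m⁻¹ are
converted to volumetric units with $\rho_0$. The $N^2$ entering $K_z$
is the trimmed mean over the thermocline interior: the fluxes cross the
thermocline, and evaluating $N^2$ exactly at an instrument depth that
may sit at (or outside) a layer edge would make $K_z$ ill-defined.

**Signs.** Depth is positive downward repo-wide; fluxes are stored
signed with positive = downward, and every flux object carries an
explicit `direction`. Report tables print upward fluxes positive and
downward fluxes negative, the display convention of two-date flux
summaries in this field.

**Uncertainty.** Three fractional sources are combined in quadrature:
sub-daily variability of $\epsilon$ (as the fractional standard error
of the daily mean), $\Gamma$ variability (20%), and the gradient
estimate (10%): $\sigma_J = |J|\sqrt{f_\epsilon^2 + 0.2^2 + 0.1^2}$.
Quadrature assumes independence; the sources are physically distinct,
and no correlation information is available to do better.

**C:N ratio.** The DIC:NOx flux ratio is computed from the flux
magnitudes; since both fluxes share the same $K_z$, the ratio equals
the gradient ratio, so only the two gradient fractions enter its
uncertainty.

**Budget.** The deep-water budget is diagnostic arithmetic, not a
prognostic model: decline rate = (start − end)/interval; apparent
removal flux = decline rate × layer depth (100 m), reported both with
and without adding back the mean downward diapycnal supply; per date,
the total flux out of the mid-water maximum $|J_{up}| + |J_{down}|$ and
the upward percentage; and the counterfactual decline without mixing =
removal flux + $|J_{down}|$. The two-date convention used throughout is
a 63-day interval and a deep-water decline of 20 mmol m⁻³ (the quoted
endpoint concentrations differ by 22; the package computes whatever its
inputs imply and forces neither reading).

## 4. Rotary spectra and forcing proxies

Shear at an instrument depth is the difference of 10 m slab means of
$u + iv$ above and below, divided by the 10 m slab-centre separation (a
grid point exactly at the target depth belongs to the upper slab; a
$\Delta z = 20$ m convention is available via `dz`). Spectra are
computed on 3.5-day, 50%-overlapping windows, demeaned, Hann-tapered by
default (power renormalised by the taper's mean square; `taper =
"none"` satisfies Parseval exactly and is used by the tests), and split
into rotary components: with the Northern-hemisphere convention used
here, clockwise motion is the negative-frequency half of the complex
series. The unsigned Nyquist bin of an even-length window is filed
under clockwise. Windows with more than 10% missing data are skipped;
the trailing incomplete window is dropped.

Band amplitudes take the nearest grid frequency (resolution
$1/3.5$ cpd) to the inertial frequency $2\Omega\sin\phi$ (1.52 cpd at
the default latitude 49.2°, which reproduces a 15.80 h period — the
latitude is a configuration default, not a claim) and to the effective
tidal frequency (mean of the M2 and S2 periods, 12.21 h = 1.97 cpd),
summing clockwise + anticlockwise power. The 3.5-day window satisfies
the Rayleigh criterion for this pair ($0.45 \times 3.5 = 1.575 \ge 1$).
The extracted quantity is spectral *power* (amplitude squared); the
distinction matters only as a fixed scale factor within a band.

Forcing proxies: the tidal-energy proxy is the 24 h centred running
mean of $|U(47\,\mathrm{m})|^3$ with a strong-tide threshold of 0.06 m³
s⁻³, and the wind proxy is $W_s \tau_s$ with a 3 W m⁻² threshold, with
$\tau_s$ from a constant-drag bulk law
($\rho_{air} = 1.22$ kg m⁻³, $C_d = 1.3\times10^{-3}$) — a deliberately
simple stress closure; any externally computed stress series can be
supplied instead.

## 5. Air–sea exchange

Oxygen solubility uses the Garcia–Gordon combined fit (Benson–Krause
coefficients; check value 274.61 µmol kg⁻¹ at 10 °C, S = 35, pinned to
4 significant figures), the Schmidt number the quartic O₂-in-seawater
polynomial (568 at 20 °C), and the transfer velocity the quadratic
wind-speed relation $k = 0.251\,u_{10}^2 (Sc/660)^{-1/2}$ cm h⁻¹. The
flux $k\,(O_2 - O_2^{sat})$ is positive for outgassing. Bubble
injection and solubility pumping by heat flux are out of scope.

## 6. What the synthetic generators emulate — and what they do not

The generators produce every input with analytic ground truth:

* **Bursts** (`gen_burst`): per-sample velocity profiles drawn from a
  Gaussian random field with fractional-Brownian covariance (Hurst
  exponent 1/3), variance-matched so spatial increments obey
  $C_2 \epsilon^{2/3} r^{2/3}$ exactly; white instrument noise
  (0.0061 m s⁻¹, the configuration's single-ping standard deviation);
  optional steady shear (default 0.005 s⁻¹) and a wave-like
  oscillating linear shear (default 0.01 m s⁻¹ at the profile edges,
  10 s period) whose combined rms shear is comparable to the turbulent
  increment scale at $\epsilon = 10^{-7}$ W kg⁻¹ — the regime where
  contamination bias matters. Samples are *independent* realizations:
  real bursts are temporally correlated, so real effective sample sizes
  are smaller and real estimator noise somewhat larger than the
  generator implies.
* **Profiles** (`gen_profiles`): an SML/linear-thermocline/deep
  temperature structure; oxygen as that background plus a Gaussian
  mid-water maximum; a co-located Gaussian chlorophyll maximum; NOx and
  DIC as ramps across the thermocline sampled at 14 and 12 bottle
  depths; Gaussian noise (0.05 °C, 1 mmol m⁻³). The June preset pins
  SML 15 m, thickness 35 m, ΔT 6 °C, O₂ {252, 273, 262} mmol m⁻³,
  NOx {0, 9} µmol l⁻¹, ΔDIC 70 µmol kg⁻¹; August deepens the SML to
  40 m and the oxygen maximum to 50 m and lowers deep O₂ to 240.
* **Mooring** (`gen_mooring`): 23 levels with banded spacing (5 m /
  2 m / 5 m / 10 m), 5-minute cadence, optional linear June→August
  drift.
* **Currents and wind** (`gen_currents`): M2 + S2 barotropic tide
  (beating at 14.77 d) with a logistic vertical structure that
  concentrates tidal shear near the thermocline base; wind events
  injecting clockwise inertial oscillations, slab-like through the
  surface layer and decaying below its base with a 10 m e-folding,
  ramping over ~0.2 d and decaying over 3 d (these scales are
  generator plumbing, exposed in the arguments, chosen to make the
  qualitative depth structure of tidal vs inertial shear reproducible).

**Dissipation ground truth is calibrated, not free.** Each scenario
carries target fluxes; the generator solves
$\Gamma \epsilon / N^2 \times \text{gradient} \times 86400 =
\text{target}$ for $\epsilon$ at each instrument depth using the
scenario's own analytic $N^2$ and gradients (one calibrating target per
depth; the remaining rows then have whatever flux the shared $K_z$
implies). This closes the loop: the pipeline's recovered fluxes can be
compared against exact analytic values.

What passing these tests shows: the chain of estimators is internally
consistent and (where unbiased routes exist) unbiased at realistic
noise levels. What it does not show: robustness to temporally
correlated turbulence, non-Gaussian wave spectra, salinity-compensated
density structure, horizontal advection, or instrument failures — real
data carry all of these.

## 7. Numerical choices and degenerate inputs

* Regressions use QR least squares; rank-deficient designs (all $r$
  equal, < 3 points) return a failure flag rather than coefficients.
* An entirely masked burst yields a missing (not zero) $\epsilon$ and
  an invalid estimate; an isothermal profile yields a no-thermocline
  flag and downstream bulk gradients refuse to compute.
* $N^2 \le 0$ makes $K_z$ undefined (error), never clipped to zero.
* Running means shrink their windows at series ends instead of padding
  with `NA`.
* Day boundaries are UTC calendar days; all timestamps are UTC.
* Seeds: every generator takes an explicit integer seed and is
  bit-identical under it.

## 8. Problem sizes used in validation

The test suite and the acceptance script use: oracle comparisons on
2-beam, 10-bin, 50-sample bursts (exhaustive pair enumeration);
recovery ensembles of 50 bursts at full instrument geometry (4 beams ×
32 bins × 300 samples); and end-to-end closure on the two-scenario pair
with 72 bursts per depth per date, a one-day 23-level mooring and a
21-day current record. These sizes give median-level statistics stable
to a few percent while keeping a full validation run in the minutes
range on a single core.

## 9. Known limitations

* The screened dissipation estimator's small-sample biases (section 1)
  are inherent to the screening rules at 300 samples per burst; users
  comparing absolute $\epsilon$ levels across instruments should be
  aware of them.
* Beam velocities are used as-is: no transformation to earth
  coordinates, no phase-unwrap reconstruction, no clock-drift handling.
* The budget is two-date diagnostic arithmetic; it cannot attribute the
  residual between supply and decline to respiration vs sediment uptake.
* Gas exchange ignores bubble-mediated supersaturation.
* File interchange is long-format CSV (`read_bursts_csv()` /
  `write_bursts_csv()` document the schema).
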