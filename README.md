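# thermoflux

Diapycnal mixing and biogeochemical flux estimation for seasonally
stratified shelf seas.

In summer-stratified shelf seas a thermocline separates a warm surface
mixed layer (SML) from cooler deep water. A subsurface chlorophyll
maximum (SCM) in the thermocline sustains a mid-water oxygen maximum, and
turbulent (diapycnal) mixing across the thermocline carries oxygen both
upward into the SML and downward into the deep layer, while supplying
nitrate and drawing down dissolved inorganic carbon (DIC). `thermoflux`
implements the full measurement-to-budget chain for this system, for
physical and biogeochemical oceanographers working with moored turbulence
and hydrographic observations:

1. **Dissipation from pulse-coherent ADCP bursts.** The rate of
   dissipation of turbulent kinetic energy, ε, is estimated from
   along-beam velocity bursts via the second-order structure function
   D<sub>LL</sub>(z, r) = C₂ ε^(2/3) r^(2/3), fitted with the three-term
   regression

   D<sub>LL</sub>(z, r) = a₀ + a₁ r^(2/3) + a₃ (r^(2/3))³

   whose cubic term (r²) isolates wave and shear contamination, so that
   ε = (a₁/C₂)^(3/2). Quality control (phase-wrap range, correlation,
   across-beam echo "fish" screening, 3-σ outliers), coefficient
   screening, and bin → beam → burst → day aggregation follow the
   conventions of the instrument literature.
2. **Stratification and gradients.** Density from the one-atmosphere
   seawater equation of state, buoyancy frequency N², SML/thermocline
   layer decomposition, and diapycnal gradients of temperature, O₂,
   nitrate+nitrite (NOx) and DIC, by direct local fits or bulk two-layer
   differences.
3. **Fluxes and the oxygen budget.** The dissipation (Osborn) method
   K<sub>z</sub> = Γ ε / N² with Γ = 0.2, scalar fluxes
   J = −K<sub>z</sub> ∂C/∂z, heat flux ρ₀ c<sub>p</sub> K<sub>z</sub>
   ∂T/∂z, quadrature uncertainty propagation, flux C:N ratios, and a
   diagnostic deep-water O₂ budget (decline rate, apparent removal flux,
   upward/downward partitioning, counterfactual decline without mixing).
4. **Mixing mechanisms.** Rotary (clockwise/anticlockwise) spectra of
   thermocline shear on 3.5-day windows, separated into the effective
   tidal band (mean of M2 and S2, 12.21 h) and the local inertial band
   (2Ω sin φ), plus wind (W<sub>s</sub>τ<sub>s</sub>) and tidal (U³)
   forcing proxies with strong-forcing thresholds.
5. **Air–sea exchange.** O₂ solubility, Schmidt number, a quadratic
   wind-speed gas-transfer velocity, and the air–sea O₂ flux.
6. **Synthetic data.** Generators for every input — Kolmogorov-scaling
   velocity bursts with prescribed ε and contamination, CTD/bottle
   profiles with a Gaussian oxygen/chlorophyll maximum and step-like
   NOx/DIC, a 23-level mooring, and M2+S2 tidal currents with
   wind-triggered inertial oscillations — all with analytic ground truth,
   so the whole pipeline can be validated end to end.

## Worked example

```r
library(thermoflux)

# one synthetic burst at a prescribed dissipation of 1e-7 W/kg
b <- gen_burst(1e-7, shear = 0.005, wave_amp = 0.01, seed = 1)
est <- estimate_epsilon(b)
est
#> <epsilon_fit> 2014-06-19 00:00:00
#>   burst-mean epsilon: 9.44e-08 W kg^-1 (4/4 beams resolved)

# dissipation + stratification + gradient -> a nitrate flux
kz <- kz_dissipation(epsilon = 1e-7, n2 = 1.587e-4, gamma = 0.2)
kz
#> <kz_estimate> K_z = 0.000126 m^2 s^-1 (eps 1e-07 W kg^-1, N^2 0.000159 s^-2, Gamma 0.2)
scalar_flux(kz, gradient = 0.257, quantity = "NOx")
#> <flux_estimate> NOx: -2.8 +/- 0.63 mmol m^-2 d^-1 (upward)
```

The flux is negative under the package's positive-downward sign
convention: nitrate is mixed **up** the concentration gradient toward the
SCM at ~2.8 mmol m⁻² d⁻¹, with the quoted uncertainty combining the Γ
(20%) and gradient (10%) fractions in quadrature.

The full synthetic pipeline — two scenario dates, three instrument
depths, 72 bursts each, mooring, profiles, currents and wind — runs in
under a minute:

```r
res <- run_pipeline(seed = 1)
print(res$flux_table, row.names = FALSE, digits = 3)
#>   date    name eps_depth_m flux_mmol_m2_d uncertainty
#>  19/06     NOx          36           3.16       0.708
#>  19/06     DIC          36          25.68       5.761
#>  19/06   O2_up          16          44.15       9.885
#>  19/06 O2_down          47          -5.03       1.129
#>  21/08     NOx          36           1.97       0.442
#>  21/08     DIC          36          16.16       3.626
#>  21/08   O2_up          36          18.03       4.046
#>  21/08 O2_down          47         -19.99       4.477
```

(upward fluxes printed positive, downward negative; exact values depend
on the seed).

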