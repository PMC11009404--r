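Package: thermoflux
Title: Diapycnal Mixing and Biogeochemical Fluxes Across a Seasonal Thermocline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating turbulent kinetic energy dissipation (epsilon)
    from pulse-coherent ADCP velocity bursts via the second-order structure
    function with a contamination-isolating three-term regression, converting
    dissipation and stratification into diapycnal diffusivity (Osborn
    dissipation method), and propagating diffusivity and scalar gradients into
    heat, oxygen, nutrient and dissolved inorganic carbon fluxes across a
    seasonal thermocline. Includes rotary spectral decomposition of current
    shear into tidal and wind-driven (near-inertial) bands, air-sea oxygen gas
    exchange, a deep-water oxygen budget, and a synthetic-data generator that
    emulates a stratified shelf-sea mooring with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
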