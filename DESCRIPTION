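Package: agrobalance
Title: Soil Greenhouse-Gas Fluxes, Water-Balance Evapotranspiration and
    Ecosystem-Service Summaries for Field-Scale Cropping Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for field-scale comparisons of annual and
    perennial bioenergy cropping systems. Converts static-chamber headspace
    concentration ramps into soil CO2 and N2O fluxes via the ideal gas law
    and linear regression, interpolates and cumulates growing-season
    emissions, computes FAO-56 Penman-Monteith reference evapotranspiration
    from daily weather, estimates actual evapotranspiration from profile
    soil-moisture sensors by a screened water-balance method with ET:PET
    gap-filling, and derives biomass, water-use efficiency, root-profile and
    nitrate-leachate summaries. Includes a synthetic-data generator with
    known ground truth (bucket-model soil moisture, chamber ramps, stochastic
    weather, leachate decline) so every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
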