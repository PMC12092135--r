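Package: oxflux
Title: Triple-Oxygen Isotope Flux-Balance Modelling of Animal Body Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state oxygen mass-balance modelling of the triple-oxygen
    isotope composition (delta-17O, delta-18O and the 17O-excess) of
    small-mammal body water. Implements the six oxygen input and eight oxygen
    output fluxes with their fractionation factors (18/16-alpha and the
    triple-isotope exponent theta), one-at-a-time parameter sensitivity
    analysis, quality control and windowed aggregation of metabolic
    phenotyping (respirometry and hopper) time series, VSMOW-SLAP
    stretching/offset correction of water-isotope analysis runs with
    control-water gating, and a seeded synthetic-data generator for
    phenotyping traces, analysis runs and body-water measurements with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
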