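Package: pm25ascvd
Title: PM2.5 Constituent Mixtures and Predicted 10-Year ASCVD Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating long-term exposure to fine particulate
    matter (PM2.5) and its six chemical constituents (black carbon, ammonium,
    nitrate, organic matter, sulfate, soil particles) to predicted 10-year
    atherosclerotic cardiovascular disease (ASCVD) risk. Implements constituent
    concentration, proportion, and residual logistic models; the isochronous
    substitution model for 1 ug/m3 reallocation between constituents;
    restricted-cubic-spline exposure-response curves with nonlinearity tests;
    stratified analyses with interaction tests; multi-timescale exposure
    averaging; and a table-driven Cox-score 10-year risk engine. A synthetic
    cohort generator with correlated constituent exposures under mass closure
    makes every stage testable end to end without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
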