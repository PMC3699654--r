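Package: drycell
Title: Single-Cell Dry Mass, Dry Density and Water Content from Dual-Fluid
    Buoyant Mass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inverts paired single-cell buoyant-mass measurements made in
    water-based and heavy-water-based fluids on a suspended microchannel
    resonator (SMR) into dry mass, dry volume, dry density, water content
    and total mass. Provides the forward physical model, empirical
    measurement-error estimation from repeat pairs, Monte-Carlo
    null-distribution machinery for dry density, systematic-bias maps for
    non-pure immersion fluids, exposure-time regressions testing for
    incomplete water exchange, population summaries (rescaled kernel
    density estimates, bootstrap medians, exact Mann-Whitney tests, Deming
    regression, logistic growth fits), and a synthetic-data generator that
    emulates dual-fluid SMR experiments with configurable noise and
    exchange dynamics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
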