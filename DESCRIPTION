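Package: pugraft
Title: Mooney-Rivlin Hyperelastic Fitting and Vascular Graft Compliance
    Simulation for Polyurethane Elastomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits the three-parameter Mooney-Rivlin hyperelastic model to
    uniaxial tensile curves of polyurethane elastomers, reports goodness of
    fit (RMSE and Lin's concordance correlation coefficient) and crosslink
    density from rubber-elasticity theory, and simulates a cylindrical
    vascular graft under sinusoidal physiological pressure to obtain
    dynamic compliance across geometry and frequency sweeps. Includes a
    synthetic tensile-curve generator with replicate jitter, measurement
    noise and hydration softening so the whole pipeline is testable
    without experimental data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
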