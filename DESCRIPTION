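Package: modkin
Title: Hyperbolic Enzyme-Modifier Kinetics for Plate-Reader Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate laws, simulation, and global nonlinear fitting for the
    general (hyperbolic, nonessential) enzyme-modifier mechanism, with
    substrate-induced (SES) inhibition kinetics, initial-velocity extraction
    from chromogenic plate-reader progress curves, mechanism classification
    into the hyperbolic modifier taxonomy, and AC50/IC50 dose-response
    analysis. Includes a synthetic plate-assay generator and a mass-action
    ODE oracle so every analysis stage can be validated without external
    data. Motivated by substrate-dependent modulation of the leukotriene A4
    hydrolase aminopeptidase activity by small-molecule modifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
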