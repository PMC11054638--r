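Package: clearperm
Title: Clearance-Based Transwell Permeability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for clearance-based permeability studies in
    Transwell-type insert systems (e.g. a TR146 buccal mucosa epithelium
    model). Computes interval clearance from basolateral time-course
    signals, fits the cleared-volume slope (PS, uL/min), applies
    series-resistance blank correction to obtain the cell-layer PS, and
    converts to apparent permeability coefficients (Papp, um/min) with
    paracellular-marker normalisation and inhibitor fold-changes. Includes
    a protocol-faithful two-compartment transport simulator with known
    ground truth, TEER barrier-integrity filtering, 2^-dCt relative qPCR
    expression, and one-/two-way ANOVA with Holm-Sidak post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
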