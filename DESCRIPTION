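Package: paleoterm
Title: Extinction Chronology and Palaeoclimate Reconstruction from Dated
    Records and Microfossil Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tools for late-Quaternary extinction chronology and
    quantitative palaeoenvironment reconstruction. Implements radiocarbon
    calibration against IntCal-style curves with highest-posterior-density
    intervals, two last-appearance estimators for series of dated records
    (the Gaussian-resampled inverse-weighted McInerny terminal-date estimator
    and a Bayesian uniform-phase boundary model), the vole-thermometer July
    temperature reconstruction, weighted-averaging partial least squares
    (WA-PLS) and modern-analogue pollen-climate transfer functions with
    leave-one-out validation, bootstrap errors and randomization tests,
    pollen biomization via plant-functional-type affinity scores, and
    rarefaction-based palynological diversity. A synthetic-data module
    generates every input with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
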