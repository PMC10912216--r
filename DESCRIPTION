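Package: hgfdyn
Title: Dynamic Pathway Modeling of HGF-Induced MET Signaling in Hepatocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Mass-action modeling and maximum-likelihood calibration of
    hepatocyte growth factor (HGF) induced signal transduction through the
    MET receptor, the MAPK cascade, the PI3K-AKT axis and mTOR signaling in
    primary hepatocytes. Provides the reference 23-species reaction network
    with steady-state pre-equilibration, multi-gel immunoblot replicate
    alignment under a combined scaling and relative-error model, absolute
    anchoring of label-free proteomics intensities, multi-start trust-region
    parameter estimation with profile-likelihood identifiability and BIC
    model selection, single-parameter diet-perturbation scans isolating the
    basal MET phosphorylation rate, adaptation of the calibrated model to
    patient-derived hepatocytes with (partial) Spearman outcome correlation,
    FUCCI cell-cycle trace classification, and synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    igraph,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
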