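Package: hemaQSP
Title: Quantitative Systems Pharmacology of Multi-Lineage Hematopoietic
    Toxicity In Vitro
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modeling of drug-induced myelosuppression in a
    six-day CD34+ multi-lineage differentiation assay. Implements a linear
    ordinary-differential-equation model of hematopoietic differentiation
    across 13 cell types (renewal, branching, death, and a quiescent
    neutrophil pool), calibration of the 27 system parameters to drug-free
    kinetic count data with a hybrid population/local-search optimizer,
    deconvolution of per-cell-type anti-proliferation and cell-killing drug
    effects (total Emax and EC50) from vehicle-normalized dose-response
    tables via a weighted L1-regularized objective, profile-likelihood
    identifiability diagnostics, classical IC50 percent-inhibition
    analysis, principal-component comparison of compound mechanism
    profiles, and a synthetic-data generator emulating the assay's donor
    replication and vehicle normalization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
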