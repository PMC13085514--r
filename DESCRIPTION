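Package: dt50prob
Title: Probabilistic Prediction of Soil Biotransformation Half-Lives
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic screening of environmental persistence in
    soil. Aggregates replicate, possibly censored, experimental DT50 values into
    per-compound Bayesian distributions of the mean log10 half-life; fits
    uncertainty-aware Gaussian-process and random-forest regressors from
    molecular structure with heteroscedastic target noise; converts predictive
    Gaussian distributions into REACH persistence-class probabilities
    (nP/P/vP); and evaluates predictive uncertainty with calibration
    diagnostics (ECE, ENCE, distance-based calibration) under nested
    cross-validation. Molecular standardization, fingerprints and 2-D
    descriptors are computed through a bundled RDKit helper script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
SystemRequirements: python (>= 3.8) with rdkit, on PATH
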