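Package: ardsvp
Title: Virtual-Patient Modelling of ARDS for Bias-Reduced Clustering of
    Multi-Hospital ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how mechanistic virtual-patient (VP)
    modelling reduces hospital-origin bias in pooled intensive-care
    cohorts with suspected acute respiratory distress syndrome (ARDS).
    Provides a steady-state multi-compartment ventilation-perfusion
    gas-exchange simulator in which ARDS is represented by closed
    (perfused, unventilated) alveolar compartments; a synthetic
    multi-hospital cohort generator with known ground truth; cohort
    preprocessing (inclusion criteria, k-anonymity exclusion,
    oxygenation-based onset detection, analysis-window extraction);
    patient matching by surrogate-based derivative-free global
    optimisation of the simulator parameters in two time windows around
    suspected onset; consensus k-means clustering with a
    consensus-matrix stability statistic and outlier labelling; and
    one-sided hypergeometric enrichment of clusters for diagnoses and
    hospital of origin with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
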