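Package: proteoscreen
Title: Integrating Baseline (Phospho)Proteomes with Phenotypic Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for relating baseline proteome and phosphoproteome
    profiles of cancer cell line panels to phenotypic drug-response screens.
    Provides readers for search-engine output tables and long-format screen
    data; median-centring normalisation and row-wise half-minimum imputation;
    four-parameter log-logistic dose-response fitting with standardised
    area-under-the-curve (AUC) scoring and plate quality control; a four-layer
    kinase activity landscape built from kinase abundance, kinase
    phosphorylation, activation-loop phosphorylation and substrate
    phosphorylation; cell-cycle phase proportion estimation from periodic
    protein clusters; sparse multiblock partial least-squares regression for
    joint drug/marker co-selection; bootstrapped elastic-net biomarker
    discovery; and TMT time-course ratio analysis with fold-change regulation
    calling. A synthetic-data generator with machine-readable planted truth
    supports end-to-end recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
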