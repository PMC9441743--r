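Package: bagnet
Title: Causal Bayesian Network Analysis of the Brain Age Gap
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for causal analysis of the brain age gap (BAG) and
    cardiovascular risk factors on synthetic cohorts with known ground
    truth. Provides structural-causal-model cohort simulation, brain-age
    regression with age-stratified cross-validation and age-bias
    correction, clinical three-level discretization, constrained NOTEARS
    continuous structure discovery, discrete Bayesian network fitting with
    Dirichlet estimation and exact variable-elimination inference,
    cross-validated node-prediction AUC validation, and observational
    versus interventional (do-operator) queries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
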