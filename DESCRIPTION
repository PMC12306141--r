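Package: idionet
Title: Idiographic Symptom Networks from Ecological Momentary Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates person-specific (idiographic) symptom networks from
    intensive longitudinal ecological momentary assessment (EMA) series and
    ranks personalized treatment targets. Implements a sparse graphical vector
    autoregression: an L1-penalised lag-1 coefficient matrix (the temporal
    network) and an L1-penalised residual precision matrix (the contemporaneous
    partial-correlation network), with both penalties selected by the extended
    Bayesian information criterion. Provides strength and bridge-strength
    centrality over clinically pre-defined symptom communities (eating-disorder
    vs. suicidality items), a treatment-target nomination stage matched to an
    editable registry of evidence-based intervention modules, and a synthetic
    EMA generator with known ground-truth network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
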