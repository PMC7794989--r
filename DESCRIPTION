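Package: empstem
Title: Ensemble Simulation of Coupled EMT-Stemness Gene Regulatory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameter-agnostic ensemble simulation of small gene regulatory
    circuits coupling epithelial-mesenchymal plasticity (miR-200/ZEB) and
    stemness (LIN28/let-7) modules. Random kinetic parameterizations are drawn
    within biologically motivated ranges, steady states are enumerated from many
    log-uniform initial conditions by stiffness-tolerant integration with Newton
    polishing, and the pooled solutions are normalized, clustered into
    epithelial/hybrid/mesenchymal phenotypes, and scored for enrichment of a
    LIN28-defined stemness window. Includes phenotypic stability factor (GRHL2,
    OVOL, NRF2) circuit variants, fold-change perturbation sweeps, link-strength
    metrics, and replicate-level significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
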