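Package: aaenorm
Title: Deep Autoencoder Normative Modelling of Regional Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Normative modelling of regional brain morphometry with a
    conditioned adversarial autoencoder. Trains the autoencoder on healthy
    reference cohorts of 101 FreeSurfer-derived regional volumes
    (Desikan-Killiany cortex plus Aseg structures), quantifies per-subject
    and per-region deviation from the healthy norm as reconstruction error,
    and benchmarks the deviation score against a linear-kernel relevance
    vector machine under a 0.632+ bootstrap scheme. Ships a synthetic
    morphometry simulator emulating graded Alzheimer's-type atrophy so the
    whole pipeline is exercisable without access-controlled cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
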