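Package: protogait
Title: Explainable Open-Set Gait Recognition from Insole Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-set gait recognition from multimodal insole recordings
    (plantar pressure, acceleration, rotation) with built-in explainability.
    Provides unit-step segmentation of continuous recordings, per-subject
    prototypes, a multimodal prototyping encoder-decoder trained with a
    combined triplet and prototype-reconstruction loss, few-shot open-set
    recognition with per-subject one-class support vector machines, and
    attribution analysis (sensitivity analysis and epsilon-stabilized
    layer-wise relevance propagation) evaluated by region perturbation.
    Includes a synthetic multimodal gait generator so the full pipeline can
    be exercised without access to proprietary insole data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
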