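Package: motorstrat
Title: Stability-Based Motor Subtyping and Kinematic Motor-Noise Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven discovery of motor subtypes in developmental
    cohorts from Movement Assessment Battery for Children (2nd edition) profiles,
    using stability-based relative clustering validation with held-out
    generalization testing and a Gaussian-null cluster significance test, and for
    quantifying per-subject motor noise from repeated reach-to-drop kinematic
    trials via multivariate dynamic time warping, with feedforward/feedback phase
    segmentation at the deceleration peak and mixed-model group inference. Includes
    a synthetic-data generator emulating multi-site motor-profile tables and
    marker-based reach trajectories, linear-model batch correction, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    clue,
    class,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    uwot,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
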