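Package: driftadapt
Title: Adaptive Multi-Day Gait Pattern Recognition Under Concept Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying concept drift in lower-limb myoelectric pattern
    recognition across measurement days. Provides a synthetic multi-day gait
    session simulator (raw multichannel signals and feature-level event streams
    with configurable day-to-day drift), EMG/kinematic signal conditioning and
    event-anchored windowing, classical time-domain feature extraction,
    mode-specific single-hidden-layer softmax network classifiers for forward
    (pre-step) and backward (post-stride) prediction, entropy-gated and
    backward-prediction based adaptation strategies, and a streaming multi-day
    evaluation protocol with error-rate, per-activity and PCA drift summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
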