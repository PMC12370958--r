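Package: pdpose
Title: Pose-Based Behavioural Phenotyping and Severity Scoring for Mouse
    Parkinson's Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for AI-based behavioural diagnosis of Parkinson's disease
    (PD) in freely moving mice from 3D pose time series. Implements motion
    episode detection and clip fragmentation from chest speed, a 340-column
    clip-level kinematic feature scheme, explicit spectro-temporal descriptors
    (Ricker wavelet entropy, fundamental frequency, wavelet scale standard
    deviation, power spectral density bandwidth, unnormalised zero-crossing
    count, zero-lag autocorrelation), gradient-boosted clip classification
    with an AI-predicted PD score (APS) and additive feature attributions,
    a randomised-tree per-stride gait classifier, turning/rearing/gait/axial
    bending event analyses, longitudinal distribution statistics via kernel
    density estimation and Kullback-Leibler divergence, behavioural task
    scores, and per-feature treatment-response categorisation. A parametric
    synthetic pose generator with ground-truth episodes and event annotations
    makes the whole pipeline testable without in-vivo recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
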