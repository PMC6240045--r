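Package: wgcdev
Title: Developmental Change in Cortical White-Gray Contrast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Vertex-wise analysis of developmental change in cortical
    white-gray contrast (WGC) for longitudinal and cross-sectional
    neurodevelopmental cohorts. Implements per-subject rate-of-change
    "angle" metrics, mean-centred task partial least squares with
    permutation testing and bootstrap ratios, a Bayesian diagnostic
    classifier with extreme-value likelihoods and sigmoid priors informed
    by bootstrap ratios, windowed-residual severity-score prediction from
    brain scores, a gradient-based motion quality-control proxy, and a
    synthetic cohort generator with planted diagnosis-dependent age
    slopes so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
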