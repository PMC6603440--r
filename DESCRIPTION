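Package: hippnorm
Title: Normative Age Nomograms for Hippocampal and Temporal Lobe Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normative, sex-specific percentile nomograms for
    hippocampal and temporal-lobe grey-matter volumes from participant-level
    image-derived phenotypes. Provides median-absolute-deviation outlier
    exclusion, linear confound regression (scanner drift, head scaling, age),
    sliding-window quantile curves with Gaussian smoothing, ratio-to-rest-of-
    grey-matter trajectory curves with a permutation test for sex differences
    in peak age, joinpoint (piecewise-linear change-point) regression on
    1-year binned means with Monte Carlo model selection, standardized effect
    sizes (Hedges' g) and group comparisons, a percentile lookup equivalent
    to a clinical nomogram chart, and a synthetic cohort generator emulating
    the statistical structure of a large population imaging study so the
    whole pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
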