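Package: citrusect
Title: Dissecting Sensory Citrus Fruit Quality Traits into Cross-Section Morphology
Version: 0.1.0
Authors@R: person("NIFTS", "Phenomics", email = "phenomics@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for relating sensorily scored citrus fruit
    quality traits (easiness of peeling, fruit hardness) to quantitative
    cross-section morphology. Generates synthetic fruit cross-section images
    with known region masks, segments the eight canonical fruit regions
    (flavedo, albedo, albedo degradation, flesh, seed, central core, core
    degradation, whole), extracts the 21 standard morphological features
    (areas, CIE L*a*b* colors, circularity, locule angles), removes year
    effects via REML/BLUP mixed models, and applies an explainable-ML battery
    (collinearity-filtered multiple linear regression, random forest with
    shadow-feature importance, partial dependence, decision-path interaction
    scores, repeated cross-validation, partial correlations), score-based
    Gaussian Bayesian-network structure learning with bootstrap arc
    confidence, and a small CNN with Grad-CAM region-relevance
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
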