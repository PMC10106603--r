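Package: yieldcast
Title: In-Season Wheat Grain Yield Prediction from Aerial NDVI and
    Agronomic Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates and validates multivariate ridge-regression models
    that predict wheat grain yield in-season from aerial NDVI combined with
    easy-to-measure agronomic traits (days to heading, plant height, ear
    density). Implements exhaustive predictor-subset search over repeated
    random training subsets with selection by the Bayesian information
    criterion, validation against an NDVI-only benchmark, stratified
    analysis of NDVI saturation above a yield threshold, broad-sense
    heritability from replicated trials, and a synthetic trial generator
    that emulates landrace/modern germplasm contrasts and saturating
    NDVI-yield relationships.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
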