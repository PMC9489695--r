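Package: socsft
Title: Space-for-Time Meta-Analysis of Soil Organic Carbon Responses to
    Warming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates depth-resolved steady-state responses of soil
    organic carbon (SOC) stocks and contents to climate warming by a
    hybrid of space-for-time substitution and random-effects
    meta-analysis.  Soil profiles are harmonized to standard depth
    intervals with a mass-preserving (equal-area) spline, missing bulk
    density and gravel are imputed with boosted regression trees, sites
    are binned into 1 degree Celsius mean-annual-temperature classes and
    matched on landform, soil order, precipitation amount and
    seasonality, and matched ambient/warm group contrasts are pooled as
    log response ratios with inverse-variance weights.  A one-pool Q10
    steady-state model links the pooled responses to the temperature
    sensitivity of decomposition, and a case-weighted random forest
    ("meta-forest") ranks environmental moderators and predicts gridded
    responses with ensemble uncertainty.  A synthetic soil-profile world
    generator with a known Q10 law provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    metafor,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
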