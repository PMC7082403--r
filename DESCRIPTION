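Package: yieldgap
Title: Boundary-Line Yield-Gap Analysis for Orchard Light-Interception Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the determinants of orchard (almond) yield
    from plot-level light-interception surveys and gridded climate products.
    Computes canopy light interception (fPAR) from paired above/below-canopy
    PAR readings, engineers monthly, seasonal, lagged and long-term climate
    features (including extreme-hot-day counts from percentile thresholds),
    estimates the light-interception yield-potential frontier by boundary-line
    analysis (upper-decile bin means with a zero-intercept regression),
    normalizes observed yields into a yield-gap statistic, and interprets the
    drivers of yield and yield gap with correlation screening, random-forest
    models (out-of-bag permutation importance, partial dependence),
    representative regression-tree rule extraction, and sixfold
    cross-validated scenario comparison (RMSE, R-squared, RPIQ). A fully
    parameterised synthetic orchard/climate/yield generator with known ground
    truth supports end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
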