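Package: growthvar
Title: Variability Analysis of Replicate Microplate Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the replicate-to-replicate variability of microbial
    growth in microplate experiments. Reads long-format plate-reader OD600
    time series, performs baseline correction and quality filtering
    (condensation trimming, outlier-yield candidates), selects the time and
    optical-density windows used to estimate yield and growth rate by
    minimizing objectives that combine the coefficient of variation with
    goodness of fit (grid search plus a Powell-style finisher), fits logistic
    growth in log-OD space with an exponential fallback, and tests
    variability differences between paired culture conditions via
    mean-normalized permutation tests, per-strain coefficient-of-variation
    ratios with an exact Wilcoxon signed-rank test on their logarithms, and
    element-contamination statistics (exact Mann-Whitney U tests combined by
    the Mudholkar-George method). Includes a synthetic-data generator with a
    saturating trace-element dose-response and heavy-tailed per-well
    contamination so the whole pipeline can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
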