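Package: phenopipe
Title: Processing and Temporal Analysis of High-Throughput Phenotyping Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for plot-level trait time series from outdoor
    high-throughput phenotyping platforms. Daily trait matrices are cleaned by
    per-day boxplot outlier masking and predictive mean matching imputation,
    genotype adjusted means (BLUEs) and heritabilities are computed day by day
    with a two-dimensional P-spline (PS-ANOVA) spatial mixed model fitted by
    REML, and the resulting genotype time series are analysed with logistic
    growth fits, kernel k-means clustering, energy-statistic change-point
    detection of an optimal time window, and a cluster-by-window analysis of
    variance. Includes a synthetic trial generator with known ground truth,
    cross-validation, between-experiment comparison, and robustness
    simulations against injected missing values and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
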