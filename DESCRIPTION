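Package: mrfa
Title: Two-Sample Mendelian Randomization of Plasma Fatty Acids and
    Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample summary-level Mendelian randomization
    with genetic instruments for plasma phospholipid fatty acid levels and
    a binary cardiovascular outcome. Implements per-SNP Wald ratios on a
    per-standard-deviation scale, fixed-effects and multiplicative
    random-effects inverse-variance-weighted pooling with Cochran Q and
    I-squared heterogeneity, the weighted-median estimator with a
    parametric bootstrap standard error, MR-Egger regression with a
    directional-pleiotropy intercept test, leave-one-out sensitivity
    analysis, Bonferroni-style significance tiers, and analytic power for
    a binary outcome. Ships a curated 22-row instrument table for ten
    fatty acids and an atrial fibrillation GWAS, plus a seeded
    summary-statistic simulator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    metafor,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
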