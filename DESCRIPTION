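Package: icuinfo
Title: Information-Theoretic Redundancy Analysis of ICU Laboratory Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the total, novel, and redundant information carried by
    longitudinal intensive-care laboratory tests. Raw measurements are reduced
    to per-patient daily medians, trimmed at the 1st and 99th percentiles,
    discretized into equal-width bins, and analyzed with plug-in estimators of
    entropy, mutual information, and conditional entropy (in bits). Includes a
    Gaussian-copula synthetic cohort generator with AR(1) day-to-day dynamics,
    monotone patient attrition, and skewed marginals, so the full pipeline can
    be exercised with known ground truth; plus tidy result tables, ggplot2
    figures, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
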