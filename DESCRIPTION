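Package: revstab
Title: Revision Instability Analysis for Repeatedly Re-Estimated Burden-of-Disease Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-epidemiological assessment of estimate instability across
    successive release iterations of burden-of-disease panels (deaths and DALYs
    attributable to risk factors). Aligns long-format estimate tables into index-year
    series and matched-year revision panels, quantifies instability with range-to-mean
    and coefficient-of-variation statistics and threshold flags, classifies later point
    estimates against earlier 95 percent uncertainty intervals, tracks ranking churn
    across iterations, and ships a seeded lognormal revision-process simulator with
    closed-form calibration targets so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
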