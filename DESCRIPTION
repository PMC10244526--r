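Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for pharmacovigilance signal detection in
    FAERS-style spontaneous adverse event report data. Reads quarterly
    ASCII extracts, cleans them (case deduplication, suspect-role
    filtering, drug-class exposure classification), maps MedDRA preferred
    terms into narrow cardiovascular Standardised MedDRA Query (SMQ)
    categories, computes shrinkage-transformed reporting odds ratios and
    information components with their 95% intervals, applies a minimum
    report-count signal rule, and profiles outcome severity by exposure
    group. A synthetic report-stream generator with exact ground truth
    supports calibration and end-to-end testing without access to the
    real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
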