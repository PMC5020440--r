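Package: ranknorms
Title: Rank-Based Social Norms Analysis of Intoxication Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether drinkers' judgements of their own
    drunkenness and its health consequences track the rank of their breath
    alcohol concentration (BrAC) within a gender-by-location reference
    group rather than its absolute level.  Provides a seeded synthetic
    street-survey cohort generator calibrated to published BrAC
    distributions, relative and asymmetrically weighted rank transforms,
    the four-model regression ladder that separates rank from absolute
    BrAC (with standardized coefficients, confidence intervals and
    variance inflation factors), grid-search estimation of the
    comparison-bias parameter eta, and a reproducible simulate-rank-fit-
    scan-report pipeline with a defined survey CSV dialect.
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
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    car,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
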