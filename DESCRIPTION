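Package: gcredist
Title: Garbage-Code Redistribution for External-Cause Mortality Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting external-cause mortality counts from
    death-registry microdata coded to ICD-10. Maps underlying causes into
    target and garbage categories, proportionally redistributes records with
    missing age, sex or year, redistributes garbage-coded deaths into valid
    external causes by either the local proportional criterion or empirical
    investigated-death reclassification fractions, applies multiplicative
    under-registration correction factors, and summarises results as directly
    age-standardized rates per 100,000 with loess trends, percent variations,
    corrected-to-registered rate ratios and state rankings. A synthetic
    microdata generator with known true causes supports validation of every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
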