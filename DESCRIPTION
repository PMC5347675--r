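Package: prrsignal
Title: Disproportionality Analysis of Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal detection for spontaneous adverse-event report databases in
    the FAERS/openFDA mould. Parses report streams (JSON-lines or flat CSV),
    builds sex-stratified drug/indication case cohorts, and computes
    proportional reporting ratios (PRR) with delta-method 95% confidence
    intervals and two-tailed Fisher exact tests, gender-composition odds
    ratios, and ranked adverse-event tables. Includes a seeded synthetic report
    generator with analytically known reporting ratios for end-to-end
    validation, drug-gene network construction with topological-coefficient
    and betweenness diagnostics and log-log power-law fits, and hypergeometric
    gene-set over-representation analysis with Benjamini-Hochberg adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    igraph,
    ggplot2,
    generics,
    yaml,
    withr,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
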