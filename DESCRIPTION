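Package: fhupm
Title: Fuzzy High-Utility Pattern Mining for Quantitative Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering high-utility itemsets in quantitative
    transaction databases, with a fuzzification front end that turns tables
    of clinical laboratory measurements into fuzzy transaction databases
    over Low/Normal/High linguistic terms. Mining is available in three
    interchangeable modes: a two-phase prefix-tree miner that generates
    candidates from overestimated node utilities and verifies them against
    exact utilities, a one-phase utility-list miner with co-occurrence and
    remaining-utility pruning, and an adaptive hybrid that starts in the
    tree phase and switches to utility-list mining per prefix. Includes
    readers and writers for common utility-transaction text formats,
    seeded synthetic data generators, a brute-force oracle for validation,
    and rendering of mined itemsets as human-readable fuzzy rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
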