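Package: atcpipe
Title: Drug Classification into Second-Level ATC Codes from Daily Dose Strings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying dispensed drugs into
    second-level Anatomical Therapeutic Chemical (ATC) codes using
    anonymized daily dose strings. Builds irreversibly anonymized
    "<drug>|<dose list>" strings from raw dispense records, classifies them
    through a prompted chain-of-thought completion backend (with a
    deterministic rule-based mock for testing), runs a search-engine
    benchmark based on regular-expression code harvesting and majority
    voting, and performs finite-population inference on graded accuracy,
    including sample-size planning with the finite population correction.
    A synthetic-data module generates multi-region dispense records and
    dose-dependent ATC truth so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
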