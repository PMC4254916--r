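Package: dwcaudit
Title: Audit and Cross-Matching of Darwin Core Triplet Specimen Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing how Darwin Core Triplet specimen identifiers
    (institutionCode:collectionCode:catalogNumber) are deployed across
    biodiversity data repositories. Recognizes canonical triplets with a
    strict grammar, coerces messy voucher strings into structured parts with
    an ordered rule set, extracts candidate identifiers from Darwin Core
    occurrence tables, GenBank flat files, BOLD specimen exports and Linkout
    URLs, classifies every identifier by completeness and syntax, and
    cross-matches corpora at tiered levels of precision (canonical,
    triplet-triplet, triplet-doublet, doublet-doublet) with distinct-key and
    ambiguity accounting. Includes a seeded synthetic-corpus generator with
    ground-truth links so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
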