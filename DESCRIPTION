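Package: feasquery
Title: Federated Feasibility Queries over FHIR Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for count-only cohort feasibility queries
    over FHIR R4 data. Implements a Structured Query model with CNF inclusion
    and DNF exclusion semantics, terminology-tree code expansion, translation
    into CQL library text and into sets of FHIR Search queries combined by set
    algebra over patient identifiers, an in-memory FHIR Search evaluator,
    privacy obfuscation of patient counts by rounding to the nearest ten, a
    pull-based multi-site broker simulation, and a deterministic synthetic-data
    generator producing planted patient cohorts with hospital-scale background
    resources plus the matching benchmark query suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
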