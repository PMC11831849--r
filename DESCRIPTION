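Package: deidr
Title: Rule-Based and Semi-Supervised De-Identification of Bilingual Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and masks protected health information (PHI) in mixed
    Korean/English clinical notes. Provides a six-category regular-expression
    rule engine (dates, staff and patient names, hospitals, regions, numbers,
    and age/sex/nationality) with overlap resolution and masking,
    pseudo-labeling of notes into BIO-tagged training corpora with a
    manual-correction workflow, a feature-based averaged-perceptron sequence
    tagger demonstrating the semi-supervised gain over the rules alone,
    token-level per-category precision/recall/F1 evaluation, and a seeded
    synthetic note generator so the whole pipeline is testable without access
    to restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stringi,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
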