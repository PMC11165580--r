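Package: enzner
Title: Dictionary and Rule-Based Enzyme Named Entity Recognition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates enzyme mentions in full-text biomedical articles with
    a two-step search engine: greedy longest-match lookup against a
    hierarchical (root-term-branched) enzyme dictionary built from EC
    nomenclature, followed by rule-based fuzzy keyword matching around
    "-ase" root words with backward and forward span extension, plus
    abbreviation resolution.  Reads and writes BioC-JSON articles with
    stand-off character-offset annotations, exports training corpora in
    SOBIE or BIO tagging schemes with stratified 75:10:15 splits, and
    scores annotation sets with Jaccard inter-annotator agreement and
    precision/recall/F1 with partial-match half credit.  A seeded
    synthetic-corpus generator with planted gold entities makes the whole
    pipeline testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
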