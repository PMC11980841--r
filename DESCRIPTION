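Package: xreact
Title: In Silico T Cell Receptor Cross-Reactivity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens a proteome for peptides potentially cross-reactive with a
    T cell receptor (TCR) of known nonamer epitope specificity. Infers a TCR
    recognition motif from a positional alanine/glycine scan (classifying each
    epitope position as MHC anchor, TCR contact, or tolerant), searches a
    proteome by exact contact-motif match, by physicochemical similarity-class
    expansion, and by exhaustive Smith-Waterman local alignment, filters
    candidates by HLA-A*02:01 binding plausibility with a pluggable predictor,
    and assembles a deduplicated candidate list with full provenance. Includes
    weight-proportional mouse/human cell-dose translation arithmetic and seeded
    synthetic-data generators (proteomes with planted ground truth, scan
    tables) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
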