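Package: mitotdrl
Title: Mitochondrial Gene Order Rearrangement Analysis by Tandem
    Duplication/Random Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for mitochondrial genome rearrangement in
    insects. Computes base composition, strand skews and codon usage
    statistics (RSCU, GC-ending ratios, codon-frequency deviation tests),
    assigns tRNA anticodon families and validates cloverleaf secondary
    structure, detects duplicated and remolded tRNA genes, scans non-coding
    regions for pseudogene remnants, G elements and tandem repeats, and
    enumerates and ranks tandem-duplication/random-loss (TDRL) scenarios
    between gene orders using pseudogene evidence. Includes a synthetic
    mitogenome simulator with recorded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
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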