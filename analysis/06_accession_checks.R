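#!/usr/bin/env Rscript
# Optional: recompute the published statistics from the deposited genome
# record. The record is not bundled; download it first, e.g.
#   curl -o KC887529.gb "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=KC887529&rettype=gb&retmode=text"
# then run
#   Rscript analysis/06_accession_checks.R KC887529.gb

suppressPackageStartupMessages(library(mitotdrl))

args <- commandArgs(trailingOnly = TRUE)
path <- if (length(args) >= 1) args[[1]] else "KC887529.gb"
if (!file.exists(path)) {
  stop("record not found at '", path,
       "'; download KC887529 from GenBank first (see the header comment)")
}
acc <- accession_report(path)
str(acc)
jsonlite::write_json(acc, "results/accession_checks.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/accession_checks.json\n")
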