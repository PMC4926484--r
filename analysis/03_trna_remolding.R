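#!/usr/bin/env Rscript
# tRNA complement of the rearranged genome: anticodon assignment, cloverleaf
# validation, the pairwise identity matrix, and remolding detection. The
# expected finding is one supernumerary Ile tRNA nearly identical to trnM
# with a single anticodon switch (CAT -> GAT).

suppressPackageStartupMessages(library(mitotdrl))

g <- parse_genome("results/simulated/rearranged.gb")
tr <- trna_genes(g)
cat("==", nrow(tr), "tRNA genes, lengths", min(tr$length), "-",
    max(tr$length), "nt ==\n")

leaf <- vapply(seq_len(nrow(tr)), function(i) {
  rep <- cloverleaf_validate(tr$sequence[i],
                             anticodon_offset = tr$anticodon_offset[i])
  paste0(ifelse(rep$valid, "valid", "INVALID"),
         ifelse(rep$arms[["D"]] == "reduced", " (reduced D arm)", ""))
}, character(1))
print(data.frame(label = tr$label, anticodon = tr$anticodon,
                 family = tr$family, length = tr$length, cloverleaf = leaf))

idm <- trna_identity_matrix(tr)
write.table(round(idm, 1), "results/trna_identity_matrix.tsv", sep = "\t",
            quote = FALSE)
cat("\nidentity trnI2 vs trnM:", round(idm["trnI2", "trnM"], 1), "%\n")
cat("identity trnI2 vs trnI1:", round(idm["trnI2", "trnI1"], 1), "%\n")

cat("\n== remolding calls ==\n")
calls <- detect_remolding(tr)
print(calls)
write.table(calls, "results/remold_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
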