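# Parsing, interval bookkeeping and gene-order extraction.

toy_genome <- function() {
  # 120 bp with three features: PCG 1..12 (J), tRNA-ish 20..40 (N),
  # "CR" 61..110; gaps 13..19, 41..60, 111..120
  seq <- paste(rep("ACGT", 30), collapse = "")
  feats <- data.frame(
    label = c("geneA", "trnX", "CR"),
    kind = c("PCG", "tRNA", "CR"),
    start = c(1L, 20L, 61L), end = c(12L, 40L, 110L),
    strand = c("J", "N", "J"), stringsAsFactors = FALSE)
  mtgenome("toy", seq, feats)
}

test_that("features carry strand-corrected slices of the reference", {
  g <- toy_genome()
  expect_equal(g$features$sequence[g$features$label == "geneA"],
               substr(g$sequence, 1, 12))
  expect_equal(g$features$sequence[g$features$label == "trnX"],
               revcomp(substr(g$sequence, 20, 40)))
  # a feature wrapping the circular origin concatenates both ends
  g2 <- mtgenome("wrap", paste(rep("ACGT", 10), collapse = ""),
                 data.frame(label = "CR", kind = "CR", start = 35L, end = 6L,
                            strand = "J", stringsAsFactors = FALSE))
  expect_equal(g2$features$sequence[1],
               paste0(substr(g2$sequence, 35, 40), substr(g2$sequence, 1, 6)))
})

test_that("coordinate validation rejects malformed features", {
  seq <- strrep("ACGT", 10)
  expect_error(mtgenome("x", seq, data.frame(
    label = "a", kind = "PCG", start = 1L, end = 99L, strand = "J")),
    "outside")
  expect_error(mtgenome("x", seq, data.frame(
    label = "a", kind = "PCG", start = 30L, end = 10L, strand = "J",
    wraps = FALSE)), "wrap")
})

test_that("GenBank writing and parsing round-trip a toy genome", {
  g <- toy_genome()
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  g2 <- parse_genome(paths[["genbank"]])
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$features[, c("label", "kind", "start", "end", "strand")],
               g$features[, c("label", "kind", "start", "end", "strand")])
  # FASTA + feature table route agrees
  g3 <- parse_genome(paths[["fasta"]], format = "fasta",
                     feature_table = paths[["features"]])
  expect_equal(g3$features$sequence, g$features$sequence)
  # parse -> write -> parse is idempotent
  paths2 <- write_genome(g2, dir, name = "again")
  g4 <- parse_genome(paths2[["genbank"]])
  expect_equal(g4$features, g2$features)
})

test_that("duplicate tRNA labels are numbered in genomic order from the CR", {
  seq <- strrep("ACGT", 50)
  feats <- data.frame(
    label = c("trnI", "CR", "trnI"),
    kind = c("tRNA", "CR", "tRNA"),
    start = c(10L, 50L, 150L), end = c(40L, 120L, 180L),
    strand = "J", stringsAsFactors = FALSE)
  g <- mtgenome("dup", seq, feats)
  # clockwise from the CR: 150..180 comes first, then (wrapping) 10..40
  expect_equal(g$features$label[g$features$start == 150L], "trnI1")
  expect_equal(g$features$label[g$features$start == 10L], "trnI2")
})

test_that("gene order extraction records strand signs and honors the origin", {
  g <- toy_genome()
  ord <- extract_gene_order(g, origin = "CR", short = FALSE)
  expect_equal(signed_labels(ord), c("CR", "geneA", "-trnX"))
  expect_error(extract_gene_order(g, origin = "nope"), "available")
  single <- mtgenome("one", strrep("ACGT", 10),
                     data.frame(label = "geneA", kind = "PCG", start = 1L,
                                end = 12L, strand = "J"))
  expect_equal(extract_gene_order(single, origin = "geneA")$labels, "geneA")
})

test_that("gene order extraction recovers the simulator's derived order", {
  for (s in c(11L, 12L, 13L)) {
    sim <- simulate_genome(paper_mimic_config(s))
    ord <- extract_gene_order(sim$genome)
    expect_true(order_equal(ord, sim$truth$derived_order),
                info = paste("seed", s))
  }
})

test_that("NCR inventory covers exactly the unannotated positions", {
  g <- toy_genome()
  ncrs <- intergenic_regions(g)
  expect_equal(ncrs$length, c(7L, 20L, 10L))
  expect_equal(attr(ncrs, "total_ncr_bp"), 37L)
  expect_equal(ncrs$flank_left[1], "geneA")
  expect_equal(ncrs$flank_right[1], "trnX")
  # abutting features leave no NCR
  ab <- mtgenome("ab", strrep("ACGT", 6),
                 data.frame(label = c("a", "b"), kind = "PCG",
                            start = c(1L, 13L), end = c(12L, 24L),
                            strand = "J"))
  expect_equal(nrow(intergenic_regions(ab)), 0L)
  expect_equal(attr(intergenic_regions(ab), "total_ncr_bp"), 0L)
  # a planted 50 bp gap is reported as one NCR of 50
  gap <- mtgenome("gap", strrep("ACGT", 20),
                  data.frame(label = c("a", "b"), kind = "PCG",
                             start = c(1L, 63L), end = c(12L, 80L),
                             strand = "J"))
  ncr2 <- intergenic_regions(gap)
  expect_equal(ncr2$length, 50L)
})

test_that("feature spans, NCRs and overlaps partition the circle", {
  for (s in c(21L, 22L)) {
    sim <- simulate_genome(paper_mimic_config(s))
    g <- sim$genome
    spans <- sum(vapply(seq_len(nrow(g$features)), function(i) {
      circular_span(g$features$start[i], g$features$end[i], g$length)
    }, integer(1)))
    ncr <- attr(intergenic_regions(g), "total_ncr_bp")
    ov <- gene_overlaps(g)
    expect_equal(spans + ncr - sum(ov$overlap_bp), g$length)
  }
})

test_that("gene overlaps report intersecting pairs with their lengths", {
  g <- toy_genome()
  expect_equal(nrow(gene_overlaps(g)), 0L)
  ovl <- mtgenome("ovl", strrep("ACGT", 10),
                  data.frame(label = c("A", "B"), kind = "PCG",
                             start = c(1L, 10L), end = c(12L, 24L),
                             strand = "J"))
  tab <- gene_overlaps(ovl)
  expect_equal(tab$overlap_bp, 3L)
  expect_setequal(c(tab$label_a, tab$label_b), c("A", "B"))
})

test_that("codon boundaries classify starts and stops", {
  mk <- function(s) mtgenome("g", s, data.frame(
    label = "p", kind = "PCG", start = 1L, end = nchar(s), strand = "J"))
  tab <- codon_boundaries(mk("ATGATTATTTAA"))
  expect_equal(tab$start_codon, "ATG")
  expect_equal(tab$stop_codon, "TAA")
  expect_true(tab$complete)
  expect_false(tab$unconventional_start)
  # length = 1 mod 3 ending in T: incomplete stop
  tab2 <- codon_boundaries(mk("GTGATTATTT"))
  expect_equal(tab2$stop_codon, "T")
  expect_false(tab2$complete)
  expect_true(tab2$unconventional_start) # GTG
  expect_error(codon_boundaries(mk("ATGATAATATAG")), NA)
  expect_error(codon_boundaries(mk("ATGT")), "shorter")
})
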