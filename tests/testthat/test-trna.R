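# Anticodon families, pairwise identity, cloverleaf validation, remolding.

test_that("anticodon lookup covers the 22 families", {
  expect_equal(anticodon_family("CAT"), "M")
  expect_equal(anticodon_family("GAT"), "I")
  expect_equal(anticodon_family("TCA"), "W")
  expect_equal(anticodon_family("TAG"), "L1")
  expect_equal(anticodon_family("GCT"), "S1")
  expect_length(anticodon_table(), 22L)
  expect_error(anticodon_family("XYZ"), "DNA")
  expect_warning(res <- anticodon_family("AAA"), "unknown")
  expect_true(is.na(res))
  # anticodons reverse-complement to codons of their family's amino acid
  code <- Biostrings::getGeneticCode("5")
  tab <- anticodon_table()
  for (ac in names(tab)) {
    fam1 <- substr(tab[[ac]], 1, 1)
    expect_equal(unname(code[revcomp(ac)]), fam1, info = ac)
  }
})

test_that("pairwise identity behaves as an alignment-based measure", {
  expect_equal(pairwise_identity("ACGT", "ACGT")$identity, 100)
  expect_equal(pairwise_identity("ACGT", "ACGT")$mismatches, 0L)
  # symmetry and the 100%-iff-identical property
  set.seed(3)
  for (i in 1:20) {
    a <- random_string(sample(4:9, 1), c("A", "C", "G", "T"))
    b <- random_string(sample(4:9, 1), c("A", "C", "G", "T"))
    ra <- pairwise_identity(a, b)
    rb <- pairwise_identity(b, a)
    expect_equal(ra$identity, rb$identity)
    if (ra$identity == 100) expect_identical(a, b)
  }
  # global scores agree with the exhaustive alignment oracle on all pairs
  # of short strings over a two-letter alphabet
  strs <- unlist(lapply(1:4, function(n) {
    apply(expand.grid(rep(list(c("A", "C")), n)), 1, paste, collapse = "")
  }))
  for (a in strs[seq(1, length(strs), 3)]) {
    for (b in strs[seq(2, length(strs), 3)]) {
      expect_equal(pairwise_identity(a, b)$score,
                   oracle_global_score(a, b), info = paste(a, b))
    }
  }
  # ungapped mode is positionwise
  u <- pairwise_identity("ACGT", "ACGA", mode = "ungapped")
  expect_equal(u$identity, 75)
  expect_error(pairwise_identity("ACGT", "ACG", mode = "ungapped"), "equal")
  # ambiguity codes are neither matches nor mismatches
  n <- pairwise_identity("ACNT", "ACGT", mode = "ungapped")
  expect_equal(n$matches, 3L)
  expect_equal(n$mismatches, 0L)
})

test_that("the simulator's cloverleaf template validates with all arms", {
  set.seed(5)
  g <- mitotdrl:::build_trna_gene("M")
  rep <- cloverleaf_validate(g$seq, anticodon_offset = g$anticodon_offset)
  expect_true(rep$valid)
  expect_equal(unname(rep$arms), rep("ok", 4))
  expect_equal(substr(g$seq, g$anticodon_offset, g$anticodon_offset + 2),
               "CAT")
  # the reduced-D variant is valid with the D arm flagged reduced
  s1 <- mitotdrl:::build_trna_gene("S1", reduced_d = TRUE)
  rep1 <- cloverleaf_validate(s1$seq, anticodon_offset = s1$anticodon_offset)
  expect_true(rep1$valid)
  expect_equal(unname(rep1$arms["D"]), "reduced")
  # scanning mode recovers the planted anticodon placement
  g2 <- mitotdrl:::build_trna_gene("W")
  rep2 <- cloverleaf_validate(g2$seq, anticodon = "TCA")
  expect_true(rep2$valid)
})

test_that("few random sequences pass the cloverleaf check", {
  set.seed(11)
  passes <- 0L
  n <- 300L
  for (i in seq_len(n)) {
    s <- random_string(70, c("A", "C", "G", "T"))
    rep <- cloverleaf_validate(s)
    if (rep$valid) passes <- passes + 1L
  }
  expect_lt(passes / n, 0.05)
})

test_that("remolding detection recovers planted remolds without false calls", {
  for (s in c(31L, 32L, 33L)) {
    sim <- simulate_genome(paper_mimic_config(s))
    tr <- trna_genes(sim$genome)
    calls <- detect_remolding(tr)
    expect_equal(nrow(calls), 1L, info = paste("seed", s))
    expect_equal(calls$label, "trnI2")
    expect_equal(calls$donor, "trnM")
    expect_equal(calls$anticodon_from, "CAT")
    expect_equal(calls$anticodon_to, "GAT")
    expect_gt(calls$identity_donor, calls$identity_own)
  }
})

test_that("mutually dissimilar tRNAs yield no remold calls", {
  set.seed(9)
  fams <- anticodon_table()
  tr <- do.call(rbind, lapply(seq_along(fams), function(i) {
    g <- mitotdrl:::build_trna_gene(fams[[i]])
    data.frame(label = paste0("trn", fams[[i]]), family = fams[[i]],
               anticodon = g$anticodon, sequence = g$seq, start = i * 100L,
               stringsAsFactors = FALSE)
  }))
  expect_equal(nrow(detect_remolding(tr)), 0L)
})

test_that("a same-family duplicate is not called a remold", {
  set.seed(10)
  g <- mitotdrl:::build_trna_gene("I")
  # a plain duplication: identical sequence, identical anticodon
  tr <- data.frame(label = c("trnI1", "trnI2", "trnM"),
                   family = c("I", "I", "M"),
                   anticodon = c("GAT", "GAT", "CAT"),
                   sequence = c(g$seq, g$seq,
                                mitotdrl:::build_trna_gene("M")$seq),
                   start = c(1L, 100L, 200L), stringsAsFactors = FALSE)
  calls <- detect_remolding(tr)
  expect_equal(nrow(calls), 0L) # own-family identity is 100, above the cap
})

test_that("remold recall is monotone in donor identity", {
  set.seed(12)
  donor <- mitotdrl:::build_trna_gene("M")
  own <- mitotdrl:::build_trna_gene("I")
  len <- nchar(donor$seq)
  recall_at <- function(n_mut) {
    hits <- 0L
    for (r in 1:10) {
      s <- donor$seq
      # switch the anticodon, then mutate n_mut other sites
      substr(s, donor$anticodon_offset, donor$anticodon_offset + 2) <- "GAT"
      ch <- strsplit(s, "")[[1]]
      pos <- sample(setdiff(seq_len(len),
                            donor$anticodon_offset:(donor$anticodon_offset + 2)),
                    n_mut)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      tr <- data.frame(label = c("trnI1", "trnI2", "trnM"),
                       family = c("I", "I", "M"),
                       anticodon = c("GAT", "GAT", "CAT"),
                       sequence = c(own$seq, paste(ch, collapse = ""),
                                    donor$seq),
                       start = c(1L, 100L, 200L), stringsAsFactors = FALSE)
      calls <- detect_remolding(tr)
      if (nrow(calls) == 1L && calls$label == "trnI2" &&
          calls$donor == "trnM") hits <- hits + 1L
    }
    hits
  }
  # divergence from the donor: 2, 8, 14 extra mutations (~97%, ~87%, ~77%)
  rec <- c(recall_at(2L), recall_at(8L), recall_at(14L))
  expect_true(all(diff(rec) <= 0))
  expect_equal(rec[1], 10L)
})
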