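# Local alignment, pseudogene remnant detection, G elements, tandem repeats.

test_that("local alignment finds embedded substrings perfectly", {
  t <- "TTTTACGTACGAAAA"
  q <- "ACGTACG"
  al <- smith_waterman(q, t)
  expect_equal(al$score, nchar(q))
  expect_equal(al$identity, 100)
  expect_equal(al$t_start, 5L)
  expect_equal(al$t_end, 11L)
  # reverse-complement-only similarity scores low in forward mode
  s <- "AAAACCCCAAAACCCCAAAA"
  al2 <- smith_waterman(revcomp(s), s)
  expect_lt(al2$score, nchar(s) / 2)
})

test_that("local alignment score is invariant under swapping the sequences", {
  set.seed(21)
  for (i in 1:30) {
    a <- random_string(sample(5:40, 1), c("A", "C", "G", "T"))
    b <- random_string(sample(5:40, 1), c("A", "C", "G", "T"))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("local alignment equals the exhaustive oracle on short pairs", {
  set.seed(22)
  # all pairs over {A,C,G} up to length 3, against full enumeration of
  # substring pairs and alignment paths
  strs <- unlist(lapply(1:3, function(n) {
    apply(expand.grid(rep(list(c("A", "C", "G")), n)), 1, paste,
          collapse = "")
  }))
  idx <- seq(1, length(strs), 4)
  for (a in strs[idx]) for (b in strs[idx]) {
    expect_equal(smith_waterman(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
  # random length 4-6 pairs against the same enumeration oracle
  for (i in 1:12) {
    a <- random_string(sample(4:6, 1))
    b <- random_string(sample(4:6, 1))
    expect_equal(smith_waterman(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment kernels agree with an established aligner", {
  # Biostrings::pairwiseAlignment as an independent cross-check; its gap
  # model charges opening once plus extension per gap base, so opening 1 /
  # extension 1 equals our open -2, extend -1, and opening 0 / extension 2
  # equals our linear -2 global gaps
  set.seed(61)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:20) {
    a <- random_string(sample(10:60, 1), c("A", "C", "G", "T"))
    b <- random_string(sample(10:60, 1), c("A", "C", "G", "T"))
    bs_local <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 1, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(smith_waterman(a, b)$score, max(0, bs_local))
    bs_global <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(pairwise_identity(a, b)$score, bs_global)
  }
})

test_that("pseudogene scan detects planted decayed copies with the right donor", {
  for (s in c(41L, 42L)) {
    sim <- simulate_genome(paper_mimic_config(s))
    hits <- pseudogene_scan(sim$genome)
    truth <- sim$truth$remnants
    big <- truth[truth$length >= 60, ]
    hit_base <- sub("[0-9]+$", "", short_label(hits$donor))
    for (r in seq_len(nrow(big))) {
      found <- any(hits$hit_start <= big$end[r] &
                     hits$hit_end >= big$start[r] &
                     hit_base == sub("[0-9]+$", "", big$donor[r]))
      expect_true(found, info = paste("seed", s, "donor", big$donor[r]))
    }
    # self-hit exclusion: no hit interval overlaps its own donor's annotation
    f <- sim$genome$features
    for (h in seq_len(nrow(hits))) {
      d <- f[f$label == hits$donor[h], ]
      if (nrow(d) == 0) next
      expect_false(hits$hit_start[h] <= d$end && hits$hit_end[h] >= d$start,
                   info = paste("hit", h))
    }
  }
})

test_that("remnant detection probability falls with planted divergence", {
  # sweep the substitution rate of the decayed ND2 copy
  det_at <- function(p, seeds) {
    found <- 0L
    for (s in seeds) {
      cfg <- paper_mimic_config(s)
      cfg$sub_prob_overrides["ND2"] <- p
      sim <- simulate_genome(cfg)
      hits <- pseudogene_scan(sim$genome)
      if (any(hits$donor == "ND2")) found <- found + 1L
    }
    found
  }
  seeds <- 51:55
  det <- c(det_at(0.05, seeds), det_at(0.25, seeds), det_at(0.45, seeds))
  expect_true(all(diff(det) <= 0))
  expect_equal(det[1], length(seeds))
  expect_equal(det[3], 0L) # 55% identity is far below the 70% floor
})

test_that("dominated weak hits are filtered, high-fidelity sub-claims kept", {
  hits <- data.frame(
    region_start = c(1L, 1L, 1L, 500L),
    region_end = 400L,
    flank_left = "x", flank_right = "y",
    donor = c("ND2", "ATP6", "CR", "COI"),
    donor_strand = "+",
    hit_start = c(10L, 50L, 200L, 600L),
    hit_end = c(300L, 90L, 290L, 640L),
    donor_start = 1L, donor_end = 50L,
    length = c(290L, 41L, 91L, 41L),
    identity = c(80, 72, 98, 71),
    mismatches = 5L,
    score = c(200, 21, 80, 20), stringsAsFactors = FALSE)
  out <- filter_dominant_hits(hits)
  # the weak ATP6 claim inside the strong ND2 interval goes; the
  # high-identity CR sub-claim and the non-overlapping COI hit stay
  expect_setequal(out$donor, c("ND2", "CR", "COI"))
})

test_that("G element scan reports maximal guanine runs on both strands", {
  expect_equal(nrow(g_element_scan("AAAA")), 0L)
  hits <- g_element_scan(paste0("ATAT", strrep("G", 10), "ATAT"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$length, 10L)
  expect_equal(hits$start, 5L)
  expect_equal(hits$strand, "+")
  # C runs are G elements of the opposite strand
  rc <- g_element_scan(paste0("AT", strrep("C", 9), "AT"))
  expect_equal(rc$strand, "-")
  expect_equal(rc$length, 9L)
  # simulated control regions carry their planted 10-bp G element
  sim <- simulate_genome(paper_mimic_config(61L))
  cr <- sim$genome$features$sequence[sim$genome$features$kind == "CR"]
  g <- g_element_scan(cr)
  expect_true(any(g$length >= 10L & g$strand == "+"))
})

test_that("tandem repeat scan finds adjacent copies and stays quiet on random DNA", {
  rep3 <- tandem_repeat_scan("ACGACGACG", min_unit = 3L)
  expect_equal(rep3$unit[1], "ACG")
  expect_equal(rep3$copy_number[1], 3)
  # approximate copies within the mismatch budget (one mismatch per copy)
  appr <- tandem_repeat_scan(paste0("ACGTACGTAC", "ACGTTCGTAC"),
                             min_unit = 10L, max_mismatch_frac = 0.1)
  expect_equal(nrow(appr), 1L)
  expect_equal(appr$copy_number[1], 2)
  # random sequence at defaults: no exact unit >= 10 repeats expected
  set.seed(31)
  empty <- 0L
  for (i in 1:10) {
    s <- random_string(500, c("A", "C", "G", "T"))
    if (nrow(tandem_repeat_scan(s)) == 0L) empty <- empty + 1L
  }
  expect_gte(empty, 9L)
})
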