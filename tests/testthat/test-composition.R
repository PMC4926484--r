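# Base composition, skews, codon usage, RSCU and the deviation test.

test_that("composition counts and skews follow their definitions", {
  comp <- composition("AATG")
  expect_equal(unname(comp$pct[c("A", "T", "G", "C")]), c(50, 25, 25, 0))
  expect_equal(comp$at_content, 75)
  # equal A and T counts give zero AT-skew
  expect_equal(composition("ATATGC")$at_skew, 0)
  # undefined skew on absent bases
  expect_true(is.na(composition("AAAA")$gc_skew))
  expect_error(composition(""), "empty")
})

test_that("skews are antisymmetric under strand complementation", {
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE,
                      prob = c(.4, .2, .1, .3)), collapse = "")
    cf <- composition(s)
    cr <- composition(revcomp(s))
    expect_equal(cr$at_skew, -cf$at_skew)
    expect_equal(cr$gc_skew, -cf$gc_skew)
  }
})

test_that("codon usage counts strand-corrected codons and flags stops", {
  g <- mtgenome("toy", "ATGATTATTTAA",
                data.frame(label = "p", kind = "PCG", start = 1L, end = 12L,
                           strand = "J"))
  cu <- codon_usage(g)
  expect_equal(cu$count[cu$codon == "ATG"], 1L)
  expect_equal(cu$count[cu$codon == "ATT"], 2L)
  expect_false("TAA" %in% cu$codon) # stops excluded from usage
  expect_equal(unname(attr(cu, "stop_counts")["TAA"]), 1L)
  # same gene annotated on the minority strand gives identical usage
  gn <- mtgenome("toy2", revcomp("ATGATTATTTAA"),
                 data.frame(label = "p", kind = "PCG", start = 1L, end = 12L,
                            strand = "N"))
  expect_equal(codon_usage(gn)$count, cu$count)
  # internal stop warns but does not fail
  gi <- mtgenome("toy3", "ATGTAAATTTAA",
                 data.frame(label = "p", kind = "PCG", start = 1L, end = 12L,
                            strand = "J"))
  expect_warning(codon_usage(gi), "internal stop")
})

test_that("RSCU matches the direct formula and conserves family sums", {
  # two-codon family with counts 3 and 1
  u <- data.frame(codon = c("GAA", "GAG"), aa = c("E", "E"), count = c(3L, 1L))
  expect_equal(rscu(u), c(1.5, 0.5))
  # uniform usage in a 4-codon family
  u4 <- data.frame(codon = c("GTT", "GTC", "GTA", "GTG"), aa = "V",
                   count = rep(5L, 4))
  expect_equal(rscu(u4), rep(1, 4))
  # random tables vs the independent oracle; family sums equal family size
  set.seed(7)
  code <- Biostrings::getGeneticCode("5")
  for (rep in 1:10) {
    u <- data.frame(codon = names(code), aa = unname(code),
                    count = rpois(length(code), 30))
    u <- u[u$aa != "*", ]
    r <- rscu(u)
    expect_equal(r, oracle_rscu(u$codon, u$aa, u$count))
    for (a in unique(u$aa)) {
      idx <- u$aa == a
      if (sum(u$count[idx]) > 0) {
        expect_equal(sum(r[idx]), sum(idx))
      }
    }
  }
})

test_that("GC-ending ratios count third positions", {
  u <- data.frame(codon = c("ATT", "ATC"), aa = "I", count = c(3L, 1L))
  gc <- gc_ending_ratio(u)
  expect_equal(gc$ratio[gc$aa == "I"], 0.25)
  u2 <- data.frame(codon = c("ATT", "ATA", "GAA"), aa = c("I", "I", "E"),
                   count = c(4L, 2L, 9L))
  gc2 <- gc_ending_ratio(u2)
  expect_equal(gc2$ratio, c(0, 0))
  expect_equal(attr(gc2, "weighted_mean"), 0)
})

test_that("the ATT/ATC deviation test matches hand-computed chi-squares", {
  panel <- data.frame(ATT = c(50, 60, 40), ATC = c(50, 60, 40))
  # target at exactly the panel proportion: no deviation
  r0 <- ile_deviation_test(c(ATT = 30, ATC = 30), panel)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  # (80, 20) against p-bar 0.5: (80-50)^2/50 + (20-50)^2/50 = 36
  r1 <- ile_deviation_test(c(ATT = 80, ATC = 20), panel)
  expect_equal(r1$statistic, 36)
  expect_lt(r1$p.value, 0.001)
  expect_equal(r1$df, 1L)
  # pooled-counts pooling uses the summed panel
  panel2 <- data.frame(ATT = c(90, 10), ATC = c(10, 90))
  rp <- ile_deviation_test(c(ATT = 50, ATC = 50), panel2,
                           pooling = "pooled_counts")
  expect_equal(rp$p_bar, 0.5)
  # small expected cells raise the caveat flag
  expect_warning(ile_deviation_test(c(ATT = 5, ATC = 1),
                                    data.frame(ATT = 9, ATC = 1)),
                 "below 5")
})
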