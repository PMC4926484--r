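# TDRL event application, scenario enumeration, remnant prediction and
# evidence ranking.

worked_source <- function() gene_order(c("CR", "I", "Q", "M", "ND2"),
                                       strands = c(1, 1, -1, 1, 1))
worked_derived <- function() gene_order(c("CR", "Q", "I2", "I1", "M", "ND2"),
                                        strands = c(1, -1, 1, 1, 1, 1))
worked_observed <- function() data.frame(
  donor = c("I", "ND2", "CR"),
  left = c("CR", "I2", "I2"), right = c("Q", "I1", "I1"),
  stringsAsFactors = FALSE)

test_that("applying a TDRL event duplicates then resolves copy fates", {
  o <- gene_order(c("CR", "I", "Q", "M", "ND2"))
  ev <- tdrl_event(c(1, 5), c("L", "R", "L", "B", "R"))
  out <- apply_tdrl(o, ev, allowed_duplicates = "M")
  expect_equal(out$labels, c("CR", "Q", "M", "I", "M", "ND2"))
  # all keep-left is the identity
  id <- apply_tdrl(o, tdrl_event(c(2, 4), c("L", "L", "L")))
  expect_true(order_equal(id, o))
  # keep_both outside the allowed set errors
  expect_error(apply_tdrl(o, tdrl_event(c(1, 2), c("B", "L"))), "keep_both")
  # strand signs ride along unchanged
  os <- gene_order(c("A", "-B", "C"))
  ev2 <- tdrl_event(c(1, 3), c("R", "L", "R"))
  expect_equal(signed_labels(apply_tdrl(os, ev2)), c("-B", "A", "C"))
})

test_that("application agrees with an independent list-rewrite oracle", {
  set.seed(41)
  labs_pool <- c("A", "B", "C", "D", "E", "F", "G")
  for (i in 1:200) {
    n <- sample(3:7, 1)
    labs <- sample(labs_pool, n)
    o <- gene_order(labs, origin = labs[1])
    bl <- sort(sample(n, 2, replace = TRUE))
    fates <- sample(c("L", "R"), bl[2] - bl[1] + 1, replace = TRUE)
    got <- apply_tdrl(o, tdrl_event(bl, fates))
    expect_equal(got$labels, oracle_apply_tdrl(labs, bl, fates))
  }
})

test_that("common-flank trimming isolates the rearranged window", {
  o <- gene_order(c("CR", "A", "B", "C"))
  expect_equal(length(trim_common_flanks(o, o)$source_window), 0L)
  # the I-Q inversion-free swap seen in flat bugs: window is the swapped pair
  a <- gene_order(c("CR", "I", "Q", "M"), origin = "CR")
  b <- gene_order(c("CR", "Q", "I", "M"), origin = "CR")
  tw <- trim_common_flanks(a, b)
  expect_equal(tw$source_window, c("I", "Q"))
  expect_equal(tw$derived_window, c("Q", "I"))
  expect_error(trim_common_flanks(gene_order("A"), gene_order("B")),
               "share no labels")
})

test_that("the worked rearrangement yields the five-pair duplication on top", {
  sc <- enumerate_single_tdrl(worked_source(), worked_derived(),
                              allowed_duplicates = "M",
                              remold_map = c(I2 = "M"))
  expect_gt(length(sc), 0L)
  ranked <- rank_scenarios(sc, worked_observed())
  top <- ranked[[1]]
  expect_equal(top$block_labels, c("CR", "I", "Q", "M", "ND2"))
  expect_equal(top$block_len, 5L)
  expect_equal(unname(top$event$fates), c("L", "R", "L", "B", "R"))
  expect_setequal(top$losses, c("CR", "I", "Q", "ND2"))
  expect_equal(top$matched, 3L)
  expect_equal(top$unmatched, 1L)
  # the predicted remnant placements
  preds <- predict_remnants(top)
  expect_equal(nrow(preds), 4L)
  expect_true(any(preds$donor == "I" & preds$left == "CR" &
                    preds$right == "Q"))
  expect_true(any(preds$donor == "ND2" & preds$left == "I2" &
                    preds$right == "I1"))
  expect_true(any(preds$donor == "CR" & preds$left == "I2" &
                    preds$right == "I1"))
  expect_true(any(preds$donor == "Q" & preds$left == "I1" &
                    preds$right == "M"))
  # the remold assignment is reported
  expect_equal(top$remolds$copy_of, "M")
  expect_equal(top$remolds$becomes, "I2")
})

test_that("identical orders need no event", {
  o <- gene_order(c("CR", "A", "B"))
  sc <- enumerate_single_tdrl(o, o)
  expect_length(sc, 0L)
  expect_true(attr(sc, "no_event_needed"))
})

test_that("every returned scenario reproduces the derived order (soundness)", {
  set.seed(43)
  for (i in 1:30) {
    n <- sample(3:5, 1)
    labs <- sample(LETTERS[1:6], n)
    src <- gene_order(labs, origin = labs[1])
    bl <- sort(sample(n, 2, replace = TRUE))
    fates <- sample(c("L", "R"), bl[2] - bl[1] + 1, replace = TRUE)
    drv <- apply_tdrl(src, tdrl_event(bl, fates))
    for (sc in enumerate_single_tdrl(src, drv)) {
      redo <- apply_tdrl(src, sc$event)
      expect_true(order_equal(redo, drv))
    }
  }
})

test_that("enumeration matches the brute-force oracle on small orders", {
  for (n in 2:4) {
    labs <- LETTERS[1:n]
    src <- gene_order(labs, origin = "A")
    events <- oracle_all_events(labs)
    derived_set <- unique(vapply(events, function(e) {
      paste(oracle_apply_tdrl(labs, e$block, e$fates), collapse = "|")
    }, character(1)))
    for (d in derived_set) {
      dl <- strsplit(d, "|", fixed = TRUE)[[1]]
      if (oracle_rot_equal(dl, labs)) next # the no-event convention
      drv <- gene_order(dl, origin = dl[1])
      got <- enumerate_single_tdrl(src, drv)
      want <- oracle_enumerate(labs, dl)
      expect_setequal(
        vapply(got, function(s) event_key(s$event$block, s$event$fates),
               character(1)),
        vapply(want, function(e) event_key(e$block, e$fates), character(1)))
    }
  }
})

test_that("prediction count equals the number of lost copies", {
  set.seed(44)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    labs <- sample(LETTERS[1:8], n)
    src <- gene_order(labs, origin = labs[1])
    bl <- sort(sample(n, 2, replace = TRUE))
    fates <- sample(c("L", "R"), bl[2] - bl[1] + 1, replace = TRUE)
    drv <- apply_tdrl(src, tdrl_event(bl, fates))
    for (sc in enumerate_single_tdrl(src, drv)) {
      expect_equal(nrow(predict_remnants(sc)), length(sc$losses))
      expect_lte(sc$block_len, n)
    }
  }
})

test_that("a sub-block scenario explains fewer remnants and ranks below", {
  sc <- enumerate_single_tdrl(worked_source(), worked_derived(),
                              allowed_duplicates = "M",
                              remold_map = c(I2 = "M"))
  ranked <- rank_scenarios(sc, worked_observed())
  sub <- Filter(function(s) identical(s$block_labels,
                                      c("I", "Q", "M", "ND2")), ranked)
  expect_gt(length(sub), 0L)
  expect_equal(sub[[1]]$matched, 2L) # psi-CR has no prediction here
  expect_gt(which(vapply(ranked, function(s)
    identical(s$block_labels, c("I", "Q", "M", "ND2")), logical(1)))[1], 1L)
  # no observed remnants: zero scores everywhere
  r0 <- rank_scenarios(sc, NULL)
  expect_true(all(vapply(r0, `[[`, integer(1), "matched") == 0L))
  # scores never exceed the number of observations
  obs <- worked_observed()
  expect_true(all(vapply(rank_scenarios(sc, obs), `[[`, integer(1),
                         "matched") <= nrow(obs)))
})

test_that("ranking is deterministic under input permutation", {
  sc <- enumerate_single_tdrl(worked_source(), worked_derived(),
                              allowed_duplicates = "M",
                              remold_map = c(I2 = "M"))
  obs <- worked_observed()
  r1 <- rank_scenarios(sc, obs)
  set.seed(1)
  r2 <- rank_scenarios(sample(sc), obs)
  k1 <- vapply(r1, function(s) event_key(s$event$block, s$event$fates),
               character(1))
  k2 <- vapply(r2, function(s) event_key(s$event$block, s$event$fates),
               character(1))
  expect_identical(k1, k2)
})

test_that("minimal event search finds 0, 1 and 2 event explanations", {
  o <- gene_order(c("I", "Q"), origin = "I")
  expect_equal(min_event_search(o, o)$k, 0L)
  # the I-Q -> Q-I swap of flat bugs; flanking genes pin the circular frame
  flip <- min_event_search(gene_order(c("CR", "I", "Q", "M")),
                           gene_order(c("CR", "Q", "I", "M")))
  expect_equal(flip$k, 1L)
  ev1 <- flip$scenarios[[1]]$event
  expect_true(all(ev1$fates %in% c("L", "R")))
  # random two-event composites on 6-label orders are explained within 2
  set.seed(46)
  for (i in 1:10) {
    labs <- sample(LETTERS[1:6])
    src <- gene_order(labs, origin = labs[1])
    mid <- src
    for (step in 1:2) {
      bl <- sort(sample(6, 2, replace = TRUE))
      fates <- sample(c("L", "R"), bl[2] - bl[1] + 1, replace = TRUE)
      mid <- apply_tdrl(mid, tdrl_event(bl, fates))
    }
    res <- min_event_search(src, mid)
    expect_lte(res$k, 2L)
  }
})

test_that("the window guard rejects oversized rearrangements with advice", {
  src <- gene_order(LETTERS[1:15], origin = "A")
  drv <- gene_order(rev(LETTERS[1:15]), origin = "A")
  expect_error(enumerate_single_tdrl(src, drv), "two-event|window")
})
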