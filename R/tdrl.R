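# Tandem-duplication/random-loss (TDRL) scenario enumeration, remnant
# prediction and evidence scoring.
#
# A TDRL event duplicates a contiguous block of genes in tandem and then
# resolves each duplicated gene pair by keeping the left copy, the right
# copy, or (for genes nominated as remold-capable) both copies. Lost copies
# decay into pseudogene remnants between their surviving neighbors, which is
# the evidence the scoring uses.

#' Construct a TDRL event
#'
#' @param block integer pair `c(i, j)`: the duplicated block as 1-based
#'   inclusive positions in the linearized source order.
#' @param fates character vector over the block positions, each
#'   `"L"` (keep left copy), `"R"` (keep right copy) or `"B"` (keep both).
#' @return object of class `tdrl_event`.
#' @export
tdrl_event <- function(block, fates) {
  block <- as.integer(block)
  stopifnot(length(block) == 2L, block[1L] >= 1L, block[2L] >= block[1L],
            length(fates) == block[2L] - block[1L] + 1L,
            all(fates %in% c("L", "R", "B")))
  structure(list(block = block, fates = fates), class = "tdrl_event")
}

#' @export
print.tdrl_event <- function(x, ...) {
  cat("<tdrl_event> block ", x$block[1L], "..", x$block[2L], ", fates ",
      paste(x$fates, collapse = ""), "\n", sep = "")
  invisible(x)
}

# full bookkeeping of one event applied to a linearized order: the tandem
# intermediate with per-copy keep/lose flags
apply_tdrl_detail <- function(order, event, allowed_duplicates = character()) {
  n <- length(order$labels)
  i <- event$block[1L]; j <- event$block[2L]
  if (j > n) stop("block ", i, "..", j, " outside order of length ", n)
  bl <- order$labels[i:j]
  if (any(event$fates == "B" & !bl %in% allowed_duplicates)) {
    bad <- bl[event$fates == "B" & !bl %in% allowed_duplicates]
    stop("keep_both not allowed for: ", paste(unique(bad), collapse = ", "))
  }
  pre <- if (i > 1L) seq_len(i - 1L) else integer(0)
  post <- if (j < n) (j + 1L):n else integer(0)
  inter <- data.frame(
    label = c(order$labels[pre], bl, bl, order$labels[post]),
    strand = c(order$strands[pre], order$strands[i:j], order$strands[i:j],
               order$strands[post]),
    copy = c(rep(0L, length(pre)), rep(1L, length(bl)), rep(2L, length(bl)),
             rep(0L, length(post))),
    src_pos = c(pre, i:j, i:j, post),
    stringsAsFactors = FALSE)
  kept <- rep(TRUE, nrow(inter))
  b1 <- length(pre) + seq_along(bl)            # first copy positions
  b2 <- length(pre) + length(bl) + seq_along(bl) # second copy positions
  kept[b1[event$fates == "R"]] <- FALSE
  kept[b2[event$fates == "L"]] <- FALSE
  inter$kept <- kept
  inter
}

#' Apply a TDRL event to a gene order
#'
#' Tandem duplication of the block followed by the per-gene copy fates.
#' Deterministic; `keep_both` is permitted only for labels in
#' `allowed_duplicates` (the remold-capable genes) and yields two copies of
#' the label in the resulting order.
#'
#' @param order a [gene_order] (operated on in its linearized frame).
#' @param event a [tdrl_event].
#' @param allowed_duplicates labels allowed to retain both copies.
#' @return the resulting [gene_order].
#' @export
apply_tdrl <- function(order, event, allowed_duplicates = character()) {
  inter <- apply_tdrl_detail(order, event, allowed_duplicates)
  surv <- inter[inter$kept, , drop = FALSE]
  gene_order(surv$label, surv$strand,
             origin = if (order$origin %in% surv$label) order$origin
                      else surv$label[1L])
}

#' Trim the common flanks of two gene orders
#'
#' Rotates both circular orders to a shared anchor label (unique in both
#' orders when possible) and removes the longest common prefix and suffix,
#' leaving the rearranged windows that any explaining duplication block must
#' cover.
#'
#' @param source,derived `gene_order` objects.
#' @return list: `source_window` and `derived_window` (signed label vectors),
#'   `prefix_len`, `suffix_len`, `anchor`, plus the two linearized signed
#'   label vectors `source_linear`, `derived_linear`.
#' @export
trim_common_flanks <- function(source, derived) {
  shared <- intersect(source$labels, derived$labels)
  if (length(shared) == 0L) stop("orders share no labels")
  uniq <- shared[vapply(shared, function(l) {
    sum(source$labels == l) == 1L && sum(derived$labels == l) == 1L
  }, logical(1L))]
  anchor <- if (source$origin %in% uniq) source$origin
            else if (length(uniq)) uniq[1L] else shared[1L]
  s <- signed_labels(rotate_to(source, anchor))
  d <- signed_labels(rotate_to(derived, anchor))
  ns <- length(s); nd <- length(d)
  p <- 0L
  while (p < min(ns, nd) && s[p + 1L] == d[p + 1L]) p <- p + 1L
  q <- 0L
  while (q < min(ns, nd) - p && s[ns - q] == d[nd - q]) q <- q + 1L
  list(source_window = if (p + q < ns) s[(p + 1L):(ns - q)] else character(0),
       derived_window = if (p + q < nd) d[(p + 1L):(nd - q)] else character(0),
       prefix_len = p, suffix_len = q, anchor = anchor,
       source_linear = s, derived_linear = d)
}

# rotation k (1-based offset) such that b[k], b[k+1], ... equals a, or NA
find_rotation <- function(a, b) {
  n <- length(a)
  if (length(b) != n) return(NA_integer_)
  for (k in seq_len(n)) {
    idx <- c(k:n, seq_len(k - 1L))
    if (identical(b[idx], a)) return(k)
  }
  NA_integer_
}

# build a full scenario record for an event whose application reproduces the
# derived order; derived_orig carries the original (pre-remold-relabel)
# derived labels for naming predictions
build_scenario <- function(source, event, allowed_duplicates, derived,
                           derived_orig_signed, remold_map) {
  inter <- apply_tdrl_detail(source, event, allowed_duplicates)
  surv <- inter[inter$kept, , drop = FALSE]
  res_signed <- ifelse(surv$strand < 0L, paste0("-", surv$label), surv$label)
  k <- find_rotation(res_signed,
                     derived_orig_signed_strip(derived_orig_signed,
                                               remold_map, source$labels))
  if (is.na(k)) return(NULL)
  nd <- length(derived_orig_signed)
  idx <- c(k:nd, seq_len(k - 1L))
  derived_names <- sub("^-", "", derived_orig_signed[idx]) # aligned with surv
  # remnant predictions: each lost copy sits between its nearest surviving
  # neighbors in the derived order
  lost <- which(!inter$kept)
  kept_pos <- which(inter$kept)
  surv_index <- match(kept_pos, kept_pos) # identity; surv row per kept pos
  preds <- NULL
  if (length(lost)) {
    m <- nrow(inter)
    left_lab <- right_lab <- character(length(lost))
    for (z in seq_along(lost)) {
      p <- lost[z]
      lpos <- kept_pos[kept_pos < p]
      l <- if (length(lpos)) max(lpos) else max(kept_pos) # circular wrap
      rpos <- kept_pos[kept_pos > p]
      r <- if (length(rpos)) min(rpos) else min(kept_pos)
      left_lab[z] <- derived_names[which(kept_pos == l)]
      right_lab[z] <- derived_names[which(kept_pos == r)]
    }
    preds <- data.frame(donor = inter$label[lost],
                        left = left_lab, right = right_lab,
                        stringsAsFactors = FALSE)
  } else {
    preds <- data.frame(donor = character(0), left = character(0),
                        right = character(0), stringsAsFactors = FALSE)
  }
  # remold assignments realized by this scenario: surviving copies whose
  # derived label differs from the source label by more than a positional
  # duplicate number (I -> I1 is renumbering, M -> I2 is a remold)
  remold_rows <- which(surv$label != derived_names &
                         surv$label != sub("[0-9]+$", "", derived_names))
  remolds <- data.frame(copy_of = surv$label[remold_rows],
                        becomes = derived_names[remold_rows],
                        stringsAsFactors = FALSE)
  structure(list(
    event = event,
    block_labels = source$labels[event$block[1L]:event$block[2L]],
    block_len = event$block[2L] - event$block[1L] + 1L,
    losses = inter$label[lost],
    predictions = preds,
    remolds = remolds,
    derived = derived,
    source = source), class = "tdrl_scenario")
}

# Relabel derived labels into the source vocabulary for matching: first the
# remold map (I2 -> M), then positional duplicate numbers are stripped when
# the source knows the base label (I1 -> I; L1 stays because the source
# carries L1 itself).
normalize_derived_labels <- function(labels, remold_map, source_labels) {
  if (!is.null(remold_map) && length(remold_map)) {
    hit <- labels %in% names(remold_map)
    labels[hit] <- unname(remold_map[labels[hit]])
  }
  miss <- !labels %in% source_labels
  stripped <- sub("[0-9]+$", "", labels[miss])
  labels[miss] <- ifelse(stripped %in% source_labels, stripped, labels[miss])
  labels
}

derived_orig_signed_strip <- function(derived_orig_signed, remold_map,
                                      source_labels) {
  lab <- sub("^-", "", derived_orig_signed)
  neg <- startsWith(derived_orig_signed, "-")
  lab <- normalize_derived_labels(lab, remold_map, source_labels)
  ifelse(neg, paste0("-", lab), lab)
}

#' @export
print.tdrl_scenario <- function(x, ...) {
  cat("<tdrl_scenario> duplicate [",
      paste(x$block_labels, collapse = "-"), "] (",
      x$block_len, " gene pairs), fates ",
      paste(x$event$fates, collapse = ""), "\n", sep = "")
  cat("  losses:", if (length(x$losses)) paste(x$losses, collapse = ", ")
      else "(none)", "\n")
  if (nrow(x$predictions)) {
    cat("  predicted remnants:\n")
    for (i in seq_len(nrow(x$predictions))) {
      cat("    psi-", x$predictions$donor[i], " between ",
          x$predictions$left[i], " and ", x$predictions$right[i], "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Enumerate single-TDRL scenarios between two gene orders
#'
#' Exhaustive search over contiguous duplication blocks and per-gene fate
#' maps for scenarios whose application transforms `source` into `derived`
#' exactly. The search is restricted to blocks covering the rearranged window
#' (after [trim_common_flanks]); blocks may extend into the conserved flanks,
#' since flank genes duplicated and resolved either way leave the order
#' unchanged but leave different remnants.
#'
#' A remolded gene in the derived order (e.g. an extra Ile tRNA that is
#' really a mutated Met duplicate) is handled through `remold_map`, which
#' relabels it to its donor before matching; scenarios then report the
#' assignment in `$remolds`.
#'
#' @param source,derived `gene_order` objects.
#' @param allowed_duplicates labels that may retain both copies (typically
#'   the donors nominated by remolding detection).
#' @param remold_map named character vector mapping derived labels to donor
#'   labels (e.g. `c(I2 = "M")`).
#' @param max_window guard on the rearranged window and block length
#'   (default 12); longer windows raise an error suggesting a two-event
#'   search or manual windowing.
#' @return list of `tdrl_scenario` objects (deduplicated by block and fate
#'   map). Identical orders yield an empty list with attribute
#'   `no_event_needed = TRUE`.
#' @export
enumerate_single_tdrl <- function(source, derived,
                                  allowed_duplicates = character(),
                                  remold_map = NULL, max_window = 12L) {
  tw <- trim_common_flanks_remold(source, derived, remold_map)
  if (length(tw$source_window) == 0L && length(tw$derived_window) == 0L) {
    return(structure(list(), no_event_needed = TRUE))
  }
  wlen <- max(length(tw$source_window), length(tw$derived_window))
  if (wlen > max_window) {
    stop("rearranged window of ", wlen, " labels exceeds the guard (",
         max_window, "); consider a two-event search or manual windowing")
  }
  ns <- length(tw$source_linear)
  p <- tw$prefix_len; q <- tw$suffix_len
  src <- gene_order(tw$source_linear, origin = sub("^-", "", tw$source_linear[1L]))
  derived_anchor <- rotate_to(derived, tw$anchor)
  derived_orig_signed <- signed_labels(derived_anchor)
  target <- derived_orig_signed_strip(derived_orig_signed, remold_map,
                                      src$labels)
  nd <- length(target)
  # rotation-invariant signed-vector equality via token search in the
  # doubled target string
  target_hay <- paste0("|", paste(c(target, target), collapse = "|"), "|")
  ssig <- signed_labels(src)
  if (ns <= max_window) {
    # small orders: search every block, which keeps the enumeration complete
    # under rotation-invariant matching
    i_hi <- ns
    j_lo <- 1L
  } else {
    # genome-scale orders: any explaining block must cover the rearranged
    # window in the anchored frame (blocks wrapping the linearization seam
    # are not searched)
    i_hi <- min(p + 1L, ns)
    j_lo <- max(ns - q, 1L)
  }
  out <- list()
  for (i in seq_len(i_hi)) {
    for (j in j_lo:ns) {
      if (j < i) next
      blen <- j - i + 1L
      if (blen > max_window) next
      bl <- src$labels[i:j]
      blk <- ssig[i:j]
      pre <- if (i > 1L) ssig[seq_len(i - 1L)] else character(0)
      post <- if (j < ns) ssig[(j + 1L):ns] else character(0)
      opts <- lapply(bl, function(l) {
        if (l %in% allowed_duplicates) c("L", "R", "B") else c("L", "R")
      })
      grid <- as.matrix(do.call(expand.grid,
                                c(opts, list(stringsAsFactors = FALSE))))
      for (r in seq_len(nrow(grid))) {
        fates <- grid[r, ]
        res <- c(pre, blk[fates != "R"], blk[fates != "L"], post)
        if (length(res) != nd) next
        if (!grepl(paste0("|", paste(res, collapse = "|"), "|"),
                   target_hay, fixed = TRUE)) next
        ev <- tdrl_event(c(i, j), unname(fates))
        sc <- build_scenario(src, ev, allowed_duplicates, derived,
                             derived_orig_signed, remold_map)
        if (is.null(sc)) next
        out[[length(out) + 1L]] <- sc
      }
    }
  }
  out
}

# trim_common_flanks after pushing the derived order through the remold map
# and duplicate-number stripping
trim_common_flanks_remold <- function(source, derived, remold_map) {
  lab <- normalize_derived_labels(derived$labels, remold_map, source$labels)
  derived2 <- gene_order(lab, derived$strands,
                         origin = if (derived$origin %in% lab) derived$origin
                                  else lab[1L])
  trim_common_flanks(source, derived2)
}

#' Predicted pseudogene remnant locations of a scenario
#' @param scenario a `tdrl_scenario`.
#' @return data.frame `donor`, `left`, `right`: each lost copy is predicted
#'   to decay between its surviving neighbor genes in the derived order.
#' @export
predict_remnants <- function(scenario) {
  stopifnot(inherits(scenario, "tdrl_scenario"))
  scenario$predictions
}

#' Concordance of a scenario with observed pseudogene remnants
#'
#' An observed remnant (donor gene plus the pair of genes flanking the NCR it
#' sits in) matches a prediction when the donors agree and the flanking pairs
#' agree as unordered sets. The score is the number of observed remnants
#' matched; predictions without observed support are counted separately and
#' not penalized (a lost copy may decay beyond recognition).
#'
#' @param scenario a `tdrl_scenario`.
#' @param observed data.frame with columns `donor`, `left`, `right`.
#' @return list: `matched`, `unmatched_predictions`.
#' @export
concordance_score <- function(scenario, observed) {
  preds <- scenario$predictions
  if (is.null(observed) || nrow(observed) == 0L) {
    return(list(matched = 0L, unmatched_predictions = nrow(preds)))
  }
  pair_match <- function(d1, l1, r1, d2, l2, r2) {
    d1 == d2 && setequal(c(l1, r1), c(l2, r2))
  }
  obs_hit <- vapply(seq_len(nrow(observed)), function(o) {
    any(vapply(seq_len(nrow(preds)), function(p) {
      pair_match(observed$donor[o], observed$left[o], observed$right[o],
                 preds$donor[p], preds$left[p], preds$right[p])
    }, logical(1L)))
  }, logical(1L))
  pred_hit <- vapply(seq_len(nrow(preds)), function(p) {
    any(vapply(seq_len(nrow(observed)), function(o) {
      pair_match(observed$donor[o], observed$left[o], observed$right[o],
                 preds$donor[p], preds$left[p], preds$right[p])
    }, logical(1L)))
  }, logical(1L))
  list(matched = sum(obs_hit), unmatched_predictions = sum(!pred_hit))
}

#' Rank TDRL scenarios by remnant evidence
#'
#' Deterministic total order: matched observed remnants (descending),
#' unmatched predictions (ascending), block length (ascending), block start
#' (ascending), then the fate string.
#'
#' @param scenarios list of `tdrl_scenario` objects.
#' @param observed observed remnants, see [concordance_score].
#' @return the scenarios, sorted, each with `$matched` and `$unmatched`
#'   filled in.
#' @export
rank_scenarios <- function(scenarios, observed) {
  if (length(scenarios) == 0L) return(scenarios)
  scored <- lapply(scenarios, function(s) {
    cs <- concordance_score(s, observed)
    s$matched <- cs$matched
    s$unmatched <- cs$unmatched_predictions
    s
  })
  keys <- vapply(scored, function(s) {
    sprintf("%05d|%05d|%05d|%05d|%s",
            99999L - s$matched, s$unmatched, s$block_len, s$event$block[1L],
            paste(s$event$fates, collapse = ""))
  }, character(1L))
  scored[order(keys)]
}

#' Minimal-event TDRL search
#'
#' Breadth-first over event counts 0, 1, 2: returns the smallest number of
#' TDRL events that transforms `source` into `derived`, with the scenarios
#' found at that count. Two-event scenarios are pairs of events applied in
#' sequence.
#'
#' @param source,derived `gene_order` objects.
#' @param allowed_duplicates labels that may retain both copies.
#' @param remold_map see [enumerate_single_tdrl].
#' @param max_events search bound (at most 2).
#' @param max_window single-event window guard; the two-event search requires
#'   the rearranged window to have at most 8 labels.
#' @return list: `k` (0, 1, 2, or NA when not explained within the bound),
#'   `scenarios` (single-event: `tdrl_scenario` list; two-event: list of
#'   `list(first_event, scenario)` pairs).
#' @export
min_event_search <- function(source, derived, allowed_duplicates = character(),
                             remold_map = NULL, max_events = 2L,
                             max_window = 12L) {
  stopifnot(max_events <= 2L)
  tw <- trim_common_flanks_remold(source, derived, remold_map)
  if (length(tw$source_window) == 0L && length(tw$derived_window) == 0L) {
    return(list(k = 0L, scenarios = list()))
  }
  one <- enumerate_single_tdrl(source, derived, allowed_duplicates,
                               remold_map, max_window)
  if (length(one) > 0L) return(list(k = 1L, scenarios = one))
  if (max_events < 2L) return(list(k = NA_integer_, scenarios = list()))
  wlen <- max(length(tw$source_window), length(tw$derived_window))
  if (wlen > 8L) {
    stop("rearranged window of ", wlen,
         " labels exceeds the two-event search guard (8)")
  }
  # first events: every block and fate map on the source; deduplicate the
  # intermediates before running the single-event search from each
  src <- gene_order(tw$source_linear,
                    origin = sub("^-", "", tw$source_linear[1L]))
  ns <- length(src$labels)
  inter_seen <- new.env(parent = emptyenv())
  found <- list()
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      if (j - i + 1L > max_window) next
      bl <- src$labels[i:j]
      opts <- lapply(bl, function(l) {
        if (l %in% allowed_duplicates) c("L", "R", "B") else c("L", "R")
      })
      grid <- do.call(expand.grid, c(opts, list(stringsAsFactors = FALSE)))
      for (r in seq_len(nrow(grid))) {
        fates <- as.character(grid[r, ])
        if (all(fates == "L") || all(fates == "R")) next # no-op events
        ev <- tdrl_event(c(i, j), fates)
        mid <- tryCatch(apply_tdrl(src, ev, allowed_duplicates),
                        error = function(e) NULL)
        if (is.null(mid)) next
        key <- paste(signed_labels(mid), collapse = "|")
        if (!is.null(inter_seen[[key]])) next
        assign(key, TRUE, envir = inter_seen)
        sec <- tryCatch(
          enumerate_single_tdrl(mid, derived, allowed_duplicates, remold_map,
                                max_window),
          error = function(e) list())
        if (length(sec) > 0L) {
          for (s2 in sec) {
            found[[length(found) + 1L]] <- list(first_event = ev,
                                                scenario = s2)
          }
        }
      }
    }
  }
  if (length(found) > 0L) return(list(k = 2L, scenarios = found))
  list(k = NA_integer_, scenarios = list())
}
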