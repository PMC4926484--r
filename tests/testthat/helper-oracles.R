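# Independent oracles used to derive expected values. These deliberately
# take naive routes (enumeration, direct formulas) so they share no code
# with the implementation they check.

# --- alignment oracles --------------------------------------------------

oracle_pair_score <- function(a, b, match, mismatch) {
  if (!a %in% c("A", "C", "G", "T") || !b %in% c("A", "C", "G", "T")) return(0)
  if (a == b) match else mismatch
}

# global alignment score by plain recursion over all alignments
# (linear gap penalty)
oracle_global_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      best <- max(best, rec(i - 1, j - 1) +
                    oracle_pair_score(ca[i], cb[j], match, mismatch))
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(ca), length(cb))
}

# best affine-gap global score of two (sub)strings by top-down recursion
# over explicit alignment paths, tracking whether the column to the right
# was a gap in either sequence (memoized on that state)
oracle_affine_global <- function(ca, cb, match, mismatch, gap_open,
                                 gap_extend) {
  n <- length(ca); m <- length(cb)
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  rec <- function(i, j, prev) {
    # prev: 0 none/diagonal, 1 gap in b, 2 gap in a
    if (i == 0 && j == 0) return(0)
    hit <- memo[i + 1, j + 1, prev + 1]
    if (!is.na(hit)) return(hit)
    best <- -Inf
    if (i > 0 && j > 0) {
      best <- max(best, rec(i - 1, j - 1, 0) +
                    oracle_pair_score(ca[i], cb[j], match, mismatch))
    }
    if (i > 0) {
      best <- max(best, rec(i - 1, j, 1) +
                    if (prev == 1) gap_extend else gap_open)
    }
    if (j > 0) {
      best <- max(best, rec(i, j - 1, 2) +
                    if (prev == 2) gap_extend else gap_open)
    }
    memo[i + 1, j + 1, prev + 1] <<- best
    best
  }
  # the cost of the LAST column depends on what follows it, so recurse from
  # the right end with "nothing follows"
  rec(n, m, 0)
}

# brute-force optimal local alignment score: best affine global score over
# every pair of substrings (the definition of local alignment)
oracle_local_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -2, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      s <- oracle_affine_global(ca[i1:i2], cb[j1:j2], match, mismatch,
                                gap_open, gap_extend)
      if (s > best) best <- s
    }
  }
  best
}

# independent R implementation of the local DP (scores only), used to
# cross-check the compiled kernel on longer pairs where full enumeration is
# impractical
oracle_local_dp <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- oracle_pair_score(ca[i], cb[j], match, mismatch)
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

random_string <- function(n, alphabet = c("A", "C", "G")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- TDRL oracles -------------------------------------------------------

# straightforward list-rewrite application of a TDRL event: duplicate the
# block as plain vectors, then drop the unwanted copies
oracle_apply_tdrl <- function(labels, block, fates) {
  i <- block[1]; j <- block[2]
  pre <- if (i > 1) labels[1:(i - 1)] else character(0)
  post <- if (j < length(labels)) labels[(j + 1):length(labels)] else character(0)
  bl <- labels[i:j]
  copy1 <- bl[fates %in% c("L", "B")]
  copy2 <- bl[fates %in% c("R", "B")]
  c(pre, copy1, copy2, post)
}

# all (block, fates) single events on an order of length n
oracle_all_events <- function(labels, allowed = character(0)) {
  n <- length(labels)
  out <- list()
  for (i in 1:n) for (j in i:n) {
    bl <- labels[i:j]
    opts <- lapply(bl, function(l) if (l %in% allowed) c("L", "R", "B")
                   else c("L", "R"))
    grid <- as.matrix(do.call(expand.grid,
                              c(opts, list(stringsAsFactors = FALSE))))
    for (r in seq_len(nrow(grid))) {
      out[[length(out) + 1]] <- list(block = c(i, j),
                                     fates = unname(grid[r, ]))
    }
  }
  out
}

rotations_of <- function(x) {
  n <- length(x)
  lapply(seq_len(n), function(k) x[c(k:n, seq_len(k - 1))[seq_len(n)]])
}

oracle_rot_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  any(vapply(rotations_of(b), identical, logical(1), y = a))
}

# brute-force set of single-TDRL explanations: every event whose rewritten
# order is a rotation of the derived labels
oracle_enumerate <- function(source_labels, derived_labels,
                             allowed = character(0)) {
  evs <- oracle_all_events(source_labels, allowed)
  Filter(function(e) {
    oracle_rot_equal(oracle_apply_tdrl(source_labels, e$block, e$fates),
                     derived_labels)
  }, evs)
}

event_key <- function(block, fates) {
  paste(block[1], block[2], paste(fates, collapse = ""))
}

# --- misc ----------------------------------------------------------------

# RSCU by the direct formula, written independently
oracle_rscu <- function(codon, aa, count) {
  out <- numeric(length(codon))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    fam <- length(idx)
    tot <- sum(count[idx])
    out[idx] <- if (tot > 0) count[idx] * fam / tot else NA_real_
  }
  out
}
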