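# tRNA analysis: anticodon inference, cloverleaf validation, duplicate and
# remolding detection.

#' Extract the tRNA complement of a genome
#'
#' Collects annotated tRNA genes with their strand-corrected sequences and
#' infers each gene's anticodon: the family expected from the label (e.g.
#' `trnI2` -> Ile -> GAT) is searched for in the sequence and the occurrence
#' giving the best cloverleaf fit is kept; if the labelled family's anticodon
#' is absent, all 22 known anticodons are tried.
#'
#' @param genome an [mtgenome].
#' @return data.frame of class `trna_set`: `label`, `family_label` (family
#'   implied by the gene name), `anticodon`, `anticodon_offset`, `family`
#'   (implied by the anticodon), `length`, `start`, `sequence`.
#' @export
trna_genes <- function(genome) {
  f <- genome$features[genome$features$kind == "tRNA", , drop = FALSE]
  rows <- lapply(seq_len(nrow(f)), function(i) {
    lab <- f$label[i]
    fam <- sub("^trn", "", lab)
    # numbered duplicates map to their base family unless the numbered name
    # is itself a family (L1/L2/S1/S2)
    fam_search <- if (fam %in% anticodon_table()) fam else sub("[0-9]+$", "", fam)
    seqi <- f$sequence[i]
    guess <- infer_anticodon(
      seqi, family = if (fam_search %in% anticodon_table()) fam_search)
    data.frame(label = lab, family_label = fam,
               anticodon = guess$anticodon,
               anticodon_offset = guess$offset,
               family = if (is.na(guess$anticodon)) NA_character_ else
                 unname(anticodon_table()[guess$anticodon]),
               length = nchar(seqi), start = f$start[i],
               sequence = seqi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trna_set", "data.frame")
  out
}

# Locate the anticodon within a tRNA gene sequence. Tries the family's
# canonical anticodon first (every occurrence), falling back to all known
# anticodons, and scores candidate offsets by cloverleaf fit.
infer_anticodon <- function(sequence, family = NULL) {
  # family labels with a numbering suffix map to their base family (I2 -> I)
  if (!is.null(family) && length(family) && !family %in% anticodon_table()) {
    family <- NULL
  }
  cands <- if (!is.null(family) && length(family)) {
    fam_base <- sub("[0-9]+$", "", family)
    acs <- names(anticodon_table())[anticodon_table() %in%
                                      c(family, fam_base,
                                        paste0(fam_base, 1:2))]
    if (length(acs)) acs else names(anticodon_table())
  } else {
    names(anticodon_table())
  }
  best <- list(anticodon = NA_character_, offset = NA_integer_, penalty = Inf)
  for (ac in cands) {
    hits <- gregexpr(ac, sequence, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    for (p in hits) {
      # the anticodon must sit in the middle half of the gene
      if (p < nchar(sequence) * 0.25 || p > nchar(sequence) * 0.75) next
      rep <- cloverleaf_validate(sequence, anticodon_offset = p)
      pen <- sum(rep$arms != "ok")
      if (pen < best$penalty) best <- list(anticodon = ac, offset = p, penalty = pen)
    }
  }
  best
}

#' Validate the cloverleaf secondary structure of a tRNA gene
#'
#' Heuristic constrained fold on the DNA gene sequence (G.T wobble counts as
#' a pair everywhere):
#' * acceptor stem: the 5'-terminal 7 nt paired against the 7 nt preceding
#'   the discriminator base (also tried without a discriminator), at most one
#'   mismatch;
#' * anticodon arm: a 7-nt loop containing the anticodon starting at loop
#'   position 2-4, closed by a stem of >= 4 pairs;
#' * D arm: a hairpin of >= 3 pairs between the acceptor stem and the
#'   anticodon stem, `reduced` when the region is present but does not fold
#'   (as in the trnS1 of most true bugs);
#' * T arm: likewise between the anticodon stem and the 3' acceptor strand.
#'
#' `valid` requires the acceptor and anticodon arms to fold; D and T arms may
#' be reduced. The check is deterministic given sequence and anticodon
#' offset. Without an offset, every occurrence of every known anticodon is
#' tried and the lowest-penalty placement is reported with a note.
#'
#' @param sequence DNA character scalar (55-90 nt).
#' @param anticodon 3-nt anticodon (used to find the offset when
#'   `anticodon_offset` is missing).
#' @param anticodon_offset 1-based start of the anticodon in `sequence`.
#' @return list of class `cloverleaf_report`: `valid`, `arms` (named flags
#'   `ok`/`reduced`/`absent` for acceptor, D, anticodon, T), `pairs` (pair
#'   counts per stem), `anticodon_offset`, `notes`.
#' @export
cloverleaf_validate <- function(sequence, anticodon = NULL,
                                anticodon_offset = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 50L || n > 90L) {
    stop("sequence length ", n, " outside the supported 50-90 nt range")
  }
  if (is.null(anticodon_offset)) {
    guess <- infer_anticodon(sequence,
                             family = if (!is.null(anticodon))
                               anticodon_family(anticodon))
    if (is.na(guess$offset)) {
      return(structure(list(valid = FALSE,
                            arms = c(acceptor = "absent", D = "absent",
                                     anticodon = "absent", T = "absent"),
                            pairs = c(acceptor = 0L, D = 0L, anticodon = 0L,
                                      T = 0L),
                            anticodon_offset = NA_integer_,
                            notes = "no plausible anticodon placement found"),
                       class = "cloverleaf_report"))
    }
    rep <- cloverleaf_validate(sequence, anticodon_offset = guess$offset)
    rep$notes <- c(rep$notes, "anticodon offset inferred by scanning")
    return(rep)
  }
  ch <- seq_chars(sequence)
  p <- as.integer(anticodon_offset)
  stopifnot(p >= 1L, p + 2L <= n)
  notes <- character(0)

  stem_pairs <- function(i5, i3) {
    # i5 ascending 5' positions, i3 ascending 3' positions; pair outermost-in
    k <- min(length(i5), length(i3))
    sum(is_wc_pair(ch[i5[seq_len(k)]], ch[rev(i3)[seq_len(k)]]))
  }

  # --- acceptor stem: try with and without a discriminator base
  acc_best <- 0L
  for (disc in c(1L, 0L)) {
    i3 <- (n - disc - 6L):(n - disc)
    if (min(i3) <= 7L) next
    acc_best <- max(acc_best, stem_pairs(1:7, i3))
  }
  acceptor <- if (acc_best >= 6L) "ok" else "absent"

  # --- anticodon arm: loop offset 2..4, stem 4-5 pairs
  ac_best <- 0L; ac_geom <- NULL
  for (o in 2:4) {
    ls <- p - o + 1L
    le <- ls + 6L
    if (ls <= 5L || le + 4L > n) next
    if (p + 2L > le) next
    for (k in 5:4) {
      if (ls - k < 1L || le + k > n) next
      pr <- stem_pairs((ls - k):(ls - 1L), (le + 1L):(le + k))
      if (pr > ac_best) {
        ac_best <- pr
        ac_geom <- list(loop_start = ls, loop_end = le, stem = k)
      }
    }
  }
  anticodon_arm <- if (ac_best >= 4L) "ok" else "absent"

  # --- D and T arms: hairpin search in the connecting regions
  hairpin <- function(from, to) {
    if (to - from + 1L < 9L) return(0L) # 3 + loop 3 + 3 minimum
    best <- 0L
    for (d in 4:3) {
      for (s1 in from:(to - 2L * d - 2L)) {
        for (loop in 3:8) {
          s2 <- s1 + d + loop
          if (s2 + d - 1L > to) break
          pr <- stem_pairs(s1:(s1 + d - 1L), s2:(s2 + d - 1L))
          if (pr >= d && pr > best) best <- pr
        }
      }
    }
    best
  }
  arm_flag <- function(pairs, from, to) {
    if (to - from + 1L < 4L) "absent" else if (pairs >= 3L) "ok" else "reduced"
  }
  d_pairs <- t_pairs <- 0L
  d_flag <- t_flag <- "absent"
  if (!is.null(ac_geom)) {
    d_from <- 8L
    d_to <- ac_geom$loop_start - ac_geom$stem - 1L
    if (d_to >= d_from) {
      d_pairs <- hairpin(d_from, d_to)
      d_flag <- arm_flag(d_pairs, d_from, d_to)
    }
    t_from <- ac_geom$loop_end + ac_geom$stem + 1L
    t_to <- n - 8L
    if (t_to >= t_from) {
      t_pairs <- hairpin(t_from, t_to)
      t_flag <- arm_flag(t_pairs, t_from, t_to)
    }
  }
  structure(list(
    valid = acceptor == "ok" && anticodon_arm == "ok",
    arms = c(acceptor = acceptor, D = d_flag, anticodon = anticodon_arm,
             T = t_flag),
    pairs = c(acceptor = acc_best, D = d_pairs, anticodon = ac_best,
              T = t_pairs),
    anticodon_offset = p, notes = notes), class = "cloverleaf_report")
}

#' @export
print.cloverleaf_report <- function(x, ...) {
  cat("cloverleaf:", if (x$valid) "valid" else "invalid", "\n  arms:",
      paste(names(x$arms), x$arms, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Detect remolded tRNA genes
#'
#' A remolded tRNA is a duplicated gene that changed decoding identity
#' through an anticodon mutation, so it resembles its donor family far more
#' than its own. A gene `g` is called a remold of donor `d` when:
#' * `g`'s family is supernumerary - at least one other tRNA of the same
#'   anticodon family exists (the remold is the extra copy; without this
#'   condition the donor of every remold would be symmetrically mis-called);
#' * global identity of `g` to `d` (a tRNA of a different family) is at
#'   least `donor_min_identity`;
#' * identity of `g` to every same-family copy is below `own_max_identity`;
#' * the two anticodons differ at 1 or 2 positions (the anticodon edit).
#'
#' Donor ties are broken by higher identity, then by genomic proximity to the
#' candidate.
#'
#' @param trnas a [trna_genes] table (or data.frame with columns `label`,
#'   `family`, `anticodon`, `sequence`, optionally `start`).
#' @param donor_min_identity percent, default 85.
#' @param own_max_identity percent, default 70.
#' @return data.frame of remold calls: `label`, `donor`, `donor_family`,
#'   `identity_donor`, `identity_own`, `anticodon_from`, `anticodon_to`,
#'   `edit_positions`, `supporting_mismatches`.
#' @export
detect_remolding <- function(trnas, donor_min_identity = 85,
                             own_max_identity = 70) {
  stopifnot(nrow(trnas) >= 2L)
  n <- nrow(trnas)
  idm <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      idm[i, j] <- idm[j, i] <-
        pairwise_identity(trnas$sequence[i], trnas$sequence[j])$identity
    }
  }
  calls <- list()
  for (i in seq_len(n)) {
    fam <- trnas$family[i]
    if (is.na(fam)) next
    own <- which(trnas$family == fam & seq_len(n) != i)
    if (length(own) == 0L) next # not a supernumerary family member
    own_id <- max(idm[i, own])
    if (own_id >= own_max_identity) next
    cross <- which(trnas$family != fam & !is.na(trnas$family))
    if (length(cross) == 0L) next
    ord <- cross[order(-idm[i, cross],
                       if (!is.null(trnas$start))
                         abs(trnas$start[cross] - trnas$start[i])
                       else seq_along(cross))]
    d <- ord[1L]
    if (idm[i, d] < donor_min_identity) next
    ac_i <- seq_chars(trnas$anticodon[i])
    ac_d <- seq_chars(trnas$anticodon[d])
    edit <- which(ac_i != ac_d)
    if (length(edit) < 1L || length(edit) > 2L) next
    al <- pairwise_identity(trnas$sequence[i], trnas$sequence[d])
    calls[[length(calls) + 1L]] <- data.frame(
      label = trnas$label[i], donor = trnas$label[d],
      donor_family = trnas$family[d],
      identity_donor = idm[i, d], identity_own = own_id,
      anticodon_from = trnas$anticodon[d], anticodon_to = trnas$anticodon[i],
      edit_positions = paste(edit, collapse = ","),
      supporting_mismatches = al$mismatches, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) {
    return(data.frame(label = character(0), donor = character(0),
                      donor_family = character(0),
                      identity_donor = numeric(0), identity_own = numeric(0),
                      anticodon_from = character(0),
                      anticodon_to = character(0),
                      edit_positions = character(0),
                      supporting_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

#' Pairwise identity matrix of a tRNA set
#' @param trnas a [trna_genes] table.
#' @return symmetric numeric matrix of percent identities.
#' @export
trna_identity_matrix <- function(trnas) {
  n <- nrow(trnas)
  m <- matrix(100, n, n, dimnames = list(trnas$label, trnas$label))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        pairwise_identity(trnas$sequence[i], trnas$sequence[j])$identity
    }
  }
  m
}
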