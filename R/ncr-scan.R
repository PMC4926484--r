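# Scanning non-coding regions for pseudogene remnants, G elements and tandem
# repeats.

#' Scan non-coding regions for pseudogene remnants
#'
#' Every NCR (and the control region, which is itself the major non-coding
#' feature) is aligned locally against every annotated gene of the same
#' genome and against its CR, in both orientations, with [smith_waterman].
#' Hits at least `min_len` aligned columns long with identity at least
#' `min_identity` are reported; hits from the same donor within the same
#' query separated by less than 10 bp in both coordinates are merged
#' (longest-interval statistics kept). A hit overlapping an annotated copy of
#' its own donor is never reported (self-hit exclusion), so the CR queried
#' against itself is skipped.
#'
#' Hits must additionally reach an alignment score of at least
#' `min_len * match`, i.e. be at least as strong as a perfect match of the
#' minimum length. Without this significance floor, the best local alignment
#' between unrelated sequences of these lengths routinely spans 20-40
#' columns at 70-80% identity (the expected optimum for random DNA under
#' +1/-1 scoring), which would bury the real remnants in noise.
#'
#' @param genome an [mtgenome].
#' @param min_len minimum aligned length in bp (default 20).
#' @param min_identity minimum percent identity (default 70).
#' @param scoring Smith-Waterman scoring vector, see [smith_waterman].
#' @param min_ncr_len only NCRs at least this long are scanned (default
#'   `min_len`).
#' @return data.frame of class `pseudo_hits`: query region (`region_start`,
#'   `region_end`, `flank_left`, `flank_right`), `donor`, `donor_strand`,
#'   genomic hit interval (`hit_start`, `hit_end`), donor-local interval
#'   (`donor_start`, `donor_end`), `length`, `identity`, `mismatches`,
#'   `score`.
#' @export
pseudogene_scan <- function(genome, min_len = 20L, min_identity = 70,
                            scoring = c(match = 1, mismatch = -1,
                                        gap_open = -2, gap_extend = -1),
                            min_ncr_len = min_len) {
  ncrs <- intergenic_regions(genome, min_len = min_ncr_len)
  f <- genome$features
  queries <- lapply(seq_len(nrow(ncrs)), function(i) {
    list(start = ncrs$start[i], end = ncrs$end[i],
         flank_left = ncrs$flank_left[i], flank_right = ncrs$flank_right[i],
         seq = feature_slice(genome$sequence, ncrs$start[i], ncrs$end[i], "J",
                             genome$length),
         is_cr = FALSE)
  })
  cr_idx <- which(f$kind == "CR")
  ncr_of_cr <- NULL
  if (length(cr_idx)) {
    i <- cr_idx[1L]
    nb <- feature_neighbors(genome, i)
    queries[[length(queries) + 1L]] <- list(
      start = f$start[i], end = f$end[i],
      flank_left = nb[1L], flank_right = nb[2L],
      seq = feature_slice(genome$sequence, f$start[i], f$end[i], "J",
                          genome$length),
      is_cr = TRUE)
  }
  hits <- list()
  for (q in queries) {
    if (nchar(q$seq) < min_len) next
    for (j in seq_len(nrow(f))) {
      if (q$is_cr && f$kind[j] == "CR") next # self-hit exclusion
      donor_seq <- f$sequence[j]
      if (nchar(donor_seq) < min_len) next
      for (orient in c("+", "-")) {
        tgt <- if (orient == "+") donor_seq else revcomp(donor_seq)
        al <- smith_waterman(q$seq, tgt, scoring = scoring)
        if (al$length < min_len || is.na(al$identity) ||
            al$identity < min_identity ||
            al$score < min_len * scoring[["match"]]) next
        hit_start <- q$start + al$q_start - 1L
        hit_end <- q$start + al$q_end - 1L
        if (hit_start > genome$length) hit_start <- hit_start - genome$length
        if (hit_end > genome$length) hit_end <- hit_end - genome$length
        ds <- if (orient == "+") al$t_start else nchar(donor_seq) - al$t_end + 1L
        de <- if (orient == "+") al$t_end else nchar(donor_seq) - al$t_start + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          region_start = q$start, region_end = q$end,
          flank_left = q$flank_left, flank_right = q$flank_right,
          donor = f$label[j], donor_strand = orient,
          hit_start = hit_start, hit_end = hit_end,
          donor_start = ds, donor_end = de,
          length = al$length, identity = al$identity,
          mismatches = al$mismatches, score = al$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(region_start = integer(0), region_end = integer(0),
                      flank_left = character(0), flank_right = character(0),
                      donor = character(0), donor_strand = character(0),
                      hit_start = integer(0), hit_end = integer(0),
                      donor_start = integer(0), donor_end = integer(0),
                      length = integer(0), identity = numeric(0),
                      mismatches = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("pseudo_hits", "data.frame")
    return(out)
  }
  out <- do.call(rbind, hits)
  out <- merge_pseudo_hits(out, gap = 10L)
  out <- out[order(-out$score, out$donor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pseudo_hits", "data.frame")
  out
}

# labels of the features flanking feature i (previous/next by position)
feature_neighbors <- function(genome, i) {
  f <- genome$features
  n <- nrow(f)
  ord <- order(f$start)
  k <- which(ord == i)
  prev <- ord[if (k == 1L) n else k - 1L]
  nxt <- ord[if (k == n) 1L else k + 1L]
  c(f$label[prev], f$label[nxt])
}

# merge same-query same-donor hits separated by < gap bp in both the query
# and donor coordinates; the merged record keeps the union interval and the
# best identity/score
merge_pseudo_hits <- function(hits, gap = 10L) {
  key <- paste(hits$region_start, hits$donor, hits$donor_strand)
  merged <- list()
  for (k in unique(key)) {
    h <- hits[key == k, , drop = FALSE]
    h <- h[order(h$hit_start), , drop = FALSE]
    cur <- h[1L, , drop = FALSE]
    if (nrow(h) > 1L) {
      for (i in 2L:nrow(h)) {
        close_q <- h$hit_start[i] - cur$hit_end <= gap
        close_d <- min(abs(h$donor_start[i] - cur$donor_end),
                       abs(cur$donor_start - h$donor_end[i])) <= gap
        if (close_q && close_d) {
          cur$hit_end <- max(cur$hit_end, h$hit_end[i])
          cur$donor_start <- min(cur$donor_start, h$donor_start[i])
          cur$donor_end <- max(cur$donor_end, h$donor_end[i])
          cur$length <- max(cur$length, h$length[i])
          cur$identity <- max(cur$identity, h$identity[i])
          cur$mismatches <- cur$mismatches + h$mismatches[i]
          cur$score <- max(cur$score, h$score[i])
        } else {
          merged[[length(merged) + 1L]] <- cur
          cur <- h[i, , drop = FALSE]
        }
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  do.call(rbind, merged)
}

#' Drop pseudogene hits dominated by a stronger overlapping hit
#'
#' Within one query region, a stretch of sequence has one true origin: when
#' two donors claim overlapping intervals, only the strongest claim is
#' credible evidence. A hit is dominated (and removed) when a strictly
#' higher-scoring hit from a different donor overlaps at least half of its
#' genomic interval and matches at least as faithfully (equal or higher
#' percent identity). The identity condition keeps a high-fidelity sub-claim
#' alive inside a longer, weaker alignment that happens to extend across it.
#' Used by the pipeline before remnant evidence is passed to scenario
#' scoring.
#'
#' @param hits a `pseudo_hits` table from [pseudogene_scan].
#' @return the filtered table.
#' @export
filter_dominant_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (i == j) next
      if (hits$region_start[i] != hits$region_start[j]) next
      if (hits$donor[i] == hits$donor[j]) next
      if (hits$score[j] <= hits$score[i]) next
      if (hits$identity[j] < hits$identity[i]) next
      ov <- min(hits$hit_end[i], hits$hit_end[j]) -
        max(hits$hit_start[i], hits$hit_start[j]) + 1L
      len_i <- hits$hit_end[i] - hits$hit_start[i] + 1L
      if (ov >= 0.5 * len_i) { keep[i] <- FALSE; break }
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for G elements (guanine runs) in a control region
#'
#' Maximal runs of G at least `min_run` long; runs of C are reported as
#' G elements on the opposite strand.
#'
#' @param cr DNA character scalar (the control-region sequence).
#' @param min_run minimum run length (default 8).
#' @return data.frame: `start`, `end`, `length`, `strand` ("+" for G runs on
#'   the given strand, "-" for C runs).
#' @export
g_element_scan <- function(cr, min_run = 8L) {
  stopifnot(nchar(cr) > 0L)
  cr <- toupper(cr)
  scan1 <- function(base, strand) {
    m <- gregexpr(paste0(base, "{", min_run, ",}"), cr)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               length = attr(m, "match.length"), strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan1("G", "+"), scan1("C", "-"))
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start), , drop = FALSE]
}

#' Scan a region for tandem repeats
#'
#' Exhaustive scan over unit lengths for runs of at least `min_copies`
#' adjacent approximate copies of a unit; a copy may mismatch the unit at up
#' to `floor(unit_length * max_mismatch_frac)` positions. A trailing partial
#' copy contributes fractionally to the copy number. Only maximal reports are
#' returned (intervals contained in another report are dropped).
#'
#' @param region DNA character scalar.
#' @param min_unit minimum repeat unit length (default 10).
#' @param min_copies minimum number of adjacent copies (default 2).
#' @param max_mismatch_frac per-copy mismatch fraction allowed (default 0,
#'   exact repeats).
#' @return data.frame of `unit`, `unit_length`, `copy_number`, `start`,
#'   `end`.
#' @export
tandem_repeat_scan <- function(region, min_unit = 10L, min_copies = 2L,
                               max_mismatch_frac = 0) {
  stopifnot(nchar(region) > 0L)
  region <- toupper(region)
  n <- nchar(region)
  raw <- charToRaw(region)
  reports <- list()
  max_unit <- n %/% min_copies
  if (max_unit >= min_unit) {
    for (u in min_unit:max_unit) {
      allowed <- floor(u * max_mismatch_frac)
      s <- 1L
      while (s + u * min_copies - 1L <= n + u - 1L && s + u - 1L <= n) {
        k <- 1L
        repeat {
          a <- s + k * u
          if (a + u - 1L > n) break
          mm <- sum(raw[s:(s + u - 1L)] != raw[a:(a + u - 1L)])
          if (mm > allowed) break
          k <- k + 1L
        }
        if (k >= min_copies) {
          end <- s + k * u - 1L
          # trailing partial copy
          tail_len <- min(u, n - end)
          part <- 0
          if (tail_len > 0L) {
            mm <- sum(raw[s:(s + tail_len - 1L)] !=
                        raw[(end + 1L):(end + tail_len)])
            if (mm <= floor(tail_len * max_mismatch_frac)) part <- tail_len / u
          }
          reports[[length(reports) + 1L]] <- data.frame(
            unit = substr(region, s, s + u - 1L), unit_length = u,
            copy_number = k + part, start = s,
            end = end + if (part > 0) tail_len else 0L,
            stringsAsFactors = FALSE)
          s <- end + 1L
        } else {
          s <- s + 1L
        }
      }
    }
  }
  if (length(reports) == 0L) {
    return(data.frame(unit = character(0), unit_length = integer(0),
                      copy_number = numeric(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, reports)
  # maximal reports only
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[i]) next
      if (out$start[j] <= out$start[i] && out$end[j] >= out$end[i] &&
          (out$end[j] - out$start[j] > out$end[i] - out$start[i])) {
        keep[i] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
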