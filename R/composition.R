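# Base composition, strand skews, codon usage, RSCU and the codon-frequency
# deviation test.

#' Strand skew
#'
#' `(a - b) / (a + b)` on counts or percentages; `NA` when the denominator is
#' zero. AT-skew is `strand_skew(A, T)`, GC-skew is `strand_skew(G, C)`.
#'
#' @param a,b counts or percentages of the two bases.
#' @return numeric in \[-1, 1\], or `NA`.
#' @export
strand_skew <- function(a, b) {
  if (a + b == 0) return(NA_real_)
  (a - b) / (a + b)
}

#' @rdname strand_skew
#' @param A,T,G,C base counts or percentages.
#' @export
at_skew <- function(A, T) strand_skew(A, T)

#' @rdname strand_skew
#' @export
gc_skew <- function(G, C) strand_skew(G, C)

#' Base composition of a genome or sequence
#'
#' Counts and percentages of the four bases on the J-strand, AT content and
#' the two strand skews. Values are kept at full precision; rounding is left
#' to presentation.
#'
#' @param x an [mtgenome] or a DNA character scalar.
#' @return list of class `composition_summary`: `counts`, `pct`, `at_content`,
#'   `at_skew`, `gc_skew`, `length`.
#' @export
composition <- function(x) {
  s <- if (inherits(x, "mtgenome")) x$sequence else toupper(x)
  if (nchar(s) == 0L) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        letters = c("A", "C", "G", "T"))
  counts <- setNames(as.integer(counts), c("A", "C", "G", "T"))
  pct <- 100 * counts / nchar(s)
  structure(list(
    counts = counts, pct = pct,
    at_content = unname(pct["A"] + pct["T"]),
    at_skew = strand_skew(counts[["A"]], counts[["T"]]),
    gc_skew = strand_skew(counts[["G"]], counts[["C"]]),
    length = nchar(s)), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("A %.1f%%  T %.1f%%  G %.1f%%  C %.1f%%  (AT %.1f%%)\n",
              x$pct[["A"]], x$pct[["T"]], x$pct[["G"]], x$pct[["C"]],
              x$at_content))
  cat(sprintf("AT-skew %.2f  GC-skew %.2f  [%d bp]\n",
              x$at_skew, x$gc_skew, x$length))
  invisible(x)
}

# codon -> amino acid map for a numeric NCBI translation table id
genetic_code <- function(translation_table = 5L) {
  Biostrings::getGeneticCode(as.character(translation_table))
}

#' Codon usage over the concatenated protein-coding genes
#'
#' Codons are read from the strand-corrected reading frame of every PCG.
#' Incomplete terminal codons are skipped; stop codons are tabulated but by
#' default excluded from usage totals (the standard RSCU convention). An
#' internal stop codon triggers a warning naming the gene and codon index
#' (annotations are not always perfect) but is not fatal.
#'
#' @param genome an [mtgenome] (or a character vector of in-frame coding
#'   sequences, strand-corrected).
#' @param translation_table NCBI genetic code id (default 5, invertebrate
#'   mitochondrial).
#' @param exclude_stops drop stop codons from the usage table?
#' @return data.frame of class `codon_usage` with `codon`, `aa`, `count`,
#'   `rscu`; attributes `translation_table`, `stop_counts`.
#' @export
codon_usage <- function(genome, translation_table = 5L, exclude_stops = TRUE) {
  seqs <- if (inherits(genome, "mtgenome")) {
    f <- genome$features
    setNames(f$sequence[f$kind == "PCG"], f$label[f$kind == "PCG"])
  } else {
    x <- as.character(genome)
    if (is.null(names(x))) names(x) <- paste0("gene", seq_along(x))
    x
  }
  if (length(seqs) == 0L) stop("no protein-coding genes available")
  code <- genetic_code(translation_table)
  counts <- setNames(integer(length(code)), names(code))
  for (g in names(seqs)) {
    s <- seqs[[g]]
    n3 <- nchar(s) %/% 3L
    if (n3 == 0L) next
    cods <- substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
    cods <- cods[grepl("^[ACGT]{3}$", cods)] # ambiguity-containing codons skipped
    internal_stop <- which(code[cods] == "*" & seq_along(cods) < length(cods))
    if (length(internal_stop) > 0L) {
      warning("internal stop codon(s) in ", g, " at codon position(s) ",
              paste(internal_stop, collapse = ", "))
    }
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  aa <- unname(code[names(counts)])
  stop_counts <- counts[aa == "*"]
  out <- data.frame(codon = names(counts), aa = aa, count = unname(counts),
                    stringsAsFactors = FALSE)
  if (exclude_stops) out <- out[out$aa != "*", , drop = FALSE]
  rownames(out) <- NULL
  out$rscu <- rscu(out)
  structure(out, class = c("codon_usage", "data.frame"),
            translation_table = translation_table, stop_counts = stop_counts)
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * family_size / sum(family counts)`: the observed count
#' divided by the expectation under uniform synonymous usage, so RSCU values
#' within one amino-acid family sum to the family size. Families with zero
#' total are reported as `NA`.
#'
#' @param usage data.frame with columns `codon`, `aa`, `count` (stop codons,
#'   if present, are ignored).
#' @return numeric vector of RSCU values aligned with `usage` rows.
#' @export
rscu <- function(usage) {
  stopifnot(all(c("codon", "aa", "count") %in% names(usage)))
  out <- rep(NA_real_, nrow(usage))
  for (a in unique(usage$aa)) {
    if (a == "*") next
    i <- which(usage$aa == a)
    tot <- sum(usage$count[i])
    if (tot > 0L) out[i] <- usage$count[i] * length(i) / tot
  }
  out
}

#' The n most used codons
#' @param usage a [codon_usage] table.
#' @param n how many.
#' @return character vector of codons, most frequent first.
#' @export
top_codons <- function(usage, n = 6L) {
  usage$codon[order(-usage$count, usage$codon)][seq_len(n)]
}

#' Per-amino-acid ratio of G/C-ending codons
#'
#' For each amino-acid family, the fraction of its codon count carried by
#' codons whose third position is G or C; the genome-level value is the
#' count-weighted mean (total G/C-ending codons over total codons).
#'
#' @param usage a [codon_usage] table.
#' @return data.frame `aa`, `gc_ending`, `total`, `ratio`; attribute
#'   `weighted_mean`.
#' @export
gc_ending_ratio <- function(usage) {
  third <- substr(usage$codon, 3L, 3L)
  gc <- third %in% c("G", "C")
  rows <- lapply(sort(unique(usage$aa)), function(a) {
    i <- usage$aa == a
    tot <- sum(usage$count[i])
    data.frame(aa = a, gc_ending = sum(usage$count[i & gc]), total = tot,
               ratio = if (tot > 0) sum(usage$count[i & gc]) / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out,
            weighted_mean = sum(out$gc_ending) / max(1L, sum(out$total)))
}

#' Chi-square deviation test for ATT vs ATC usage
#'
#' Goodness-of-fit test of one species' isoleucine codon split (ATT vs ATC)
#' against the expectation derived from a reference panel of species, under
#' the null hypothesis that the relative frequency of ATT vs ATC is the same
#' across species. The expected ATT proportion is either the mean of the
#' panel's per-species proportions (default) or the proportion in the pooled
#' panel counts.
#'
#' @param target counts for the tested species, a length-2 vector
#'   `c(ATT = , ATC = )`.
#' @param panel matrix or data.frame of panel counts with columns `ATT`, `ATC`
#'   (one row per species).
#' @param pooling `"mean_of_proportions"` or `"pooled_counts"`.
#' @return list of class `ile_deviation_test`: `statistic`, `df`, `p.value`,
#'   `expected`, `p_bar`, `observed`, `small_expected` (TRUE when an expected
#'   cell is below 5, a small-sample caveat).
#' @export
ile_deviation_test <- function(target, panel,
                               pooling = c("mean_of_proportions",
                                           "pooled_counts")) {
  pooling <- match.arg(pooling)
  target <- unlist(target)
  if (!is.null(names(target)) && all(c("ATT", "ATC") %in% names(target))) {
    target <- target[c("ATT", "ATC")]
  }
  stopifnot(length(target) == 2L, sum(target) > 0)
  panel <- as.matrix(as.data.frame(panel)[, c("ATT", "ATC")])
  stopifnot(nrow(panel) > 0L)
  p_bar <- switch(pooling,
    mean_of_proportions = mean(panel[, "ATT"] / rowSums(panel)),
    pooled_counts = sum(panel[, "ATT"]) / sum(panel))
  n <- sum(target)
  expected <- c(ATT = n * p_bar, ATC = n * (1 - p_bar))
  small <- any(expected < 5)
  if (small) warning("expected cell count below 5; chi-square approximation is weak")
  statistic <- sum((target - expected)^2 / expected)
  structure(list(statistic = statistic, df = 1L,
                 p.value = pchisq(statistic, df = 1L, lower.tail = FALSE),
                 expected = expected, p_bar = p_bar,
                 observed = c(ATT = unname(target[1L]), ATC = unname(target[2L])),
                 pooling = pooling, small_expected = small),
            class = "ile_deviation_test")
}

#' @export
print.ile_deviation_test <- function(x, ...) {
  cat(sprintf(
    "ATT/ATC deviation test (%s): chi2 = %.3f, df = 1, p = %.4g\n",
    x$pooling, x$statistic, x$p.value))
  cat(sprintf("  observed ATT %d / ATC %d, expected %.1f / %.1f (p_bar %.3f)\n",
              x$observed[1L], x$observed[2L], x$expected[1L], x$expected[2L],
              x$p_bar))
  invisible(x)
}
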