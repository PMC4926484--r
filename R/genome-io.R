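# Reading, writing and interval bookkeeping for annotated circular
# mitochondrial genomes. Coordinates are 1-based inclusive on the J-strand
# reference, as in GenBank; a feature spanning the circular origin has
# end < start and wraps = TRUE.

FEATURE_KINDS <- c("PCG", "rRNA", "tRNA", "CR")

#' Construct an annotated circular mitogenome
#'
#' @param id accession or sample name.
#' @param sequence J-strand nucleotide string (circular).
#' @param features data.frame with columns `label`, `kind` (PCG/rRNA/tRNA/CR),
#'   `start`, `end` (1-based inclusive), `strand` ("J"/"N"); an optional
#'   `wraps` column marks features spanning the circular origin.
#' @param normalize_labels rename duplicate tRNA labels with positional
#'   numbers (going clockwise from the origin feature) when the annotation
#'   does not number them itself.
#' @return object of class `mtgenome`: features are sorted by start and carry
#'   strand-corrected 5'->3' sequences.
#' @export
mtgenome <- function(id, sequence, features, normalize_labels = TRUE) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  stopifnot(is.data.frame(features),
            all(c("label", "kind", "start", "end", "strand") %in% names(features)))
  f <- features
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  if (is.null(f$wraps)) f$wraps <- f$end < f$start
  f$wraps <- as.logical(f$wraps)
  bad <- f$start < 1L | f$start > len | f$end < 1L | f$end > len
  if (any(bad)) {
    stop("feature coordinates outside sequence (length ", len, "): ",
         paste(f$label[bad], collapse = ", "))
  }
  if (any(f$end < f$start & !f$wraps)) {
    stop("feature with end < start but no circular wrap flag: ",
         paste(f$label[f$end < f$start & !f$wraps], collapse = ", "))
  }
  if (!all(f$kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind(s): ",
         paste(setdiff(unique(f$kind), FEATURE_KINDS), collapse = ", "))
  }
  stopifnot(all(f$strand %in% c("J", "N")))
  f <- f[order(f$start), , drop = FALSE]
  rownames(f) <- NULL
  f$sequence <- vapply(seq_len(nrow(f)), function(i) {
    feature_slice(sequence, f$start[i], f$end[i], f$strand[i], len)
  }, character(1L))
  g <- structure(list(id = id, sequence = sequence, length = len, features = f),
                 class = "mtgenome")
  if (normalize_labels) g <- normalize_duplicate_labels(g)
  if (anyDuplicated(g$features$label)) {
    stop("duplicate feature labels after normalization: ",
         paste(unique(g$features$label[duplicated(g$features$label)]),
               collapse = ", "))
  }
  g
}

#' @export
print.mtgenome <- function(x, ...) {
  cat("<mtgenome> ", x$id, ": ", x$length, " bp, ", nrow(x$features),
      " features (", sum(x$features$kind == "PCG"), " PCG, ",
      sum(x$features$kind == "rRNA"), " rRNA, ",
      sum(x$features$kind == "tRNA"), " tRNA, ",
      sum(x$features$kind == "CR"), " CR)\n", sep = "")
  invisible(x)
}

# strand-corrected 5'->3' slice of the circular reference
feature_slice <- function(sequence, start, end, strand, len = nchar(sequence)) {
  s <- if (start <= end) {
    substr(sequence, start, end)
  } else {
    paste0(substr(sequence, start, len), substr(sequence, 1L, end))
  }
  if (strand == "N") revcomp(s) else s
}

# Number duplicated labels in genomic order, starting from the origin feature
# (CR when present) going clockwise. Annotations that already number their
# duplicates are left alone.
normalize_duplicate_labels <- function(genome) {
  f <- genome$features
  dup <- unique(f$label[duplicated(f$label)])
  if (length(dup) == 0L) return(genome)
  anchor <- which(f$kind == "CR")[1L]
  if (is.na(anchor)) anchor <- 1L
  ord <- c(anchor:nrow(f), seq_len(anchor - 1L))[seq_len(nrow(f))]
  for (lab in dup) {
    idx <- ord[f$label[ord] == lab]
    f$label[idx] <- paste0(lab, seq_along(idx))
  }
  genome$features <- f
  genome
}

#' Parse an annotated mitogenome from disk
#'
#' Reads either a GenBank flat file (LOCUS/FEATURES/ORIGIN) or a FASTA file
#' accompanied by a tab-separated feature table with columns `label`, `kind`,
#' `start`, `end`, `strand`.
#'
#' @param path GenBank or FASTA file.
#' @param format `"genbank"` or `"fasta"`; `"auto"` decides from the file
#'   contents.
#' @param feature_table TSV path (required for FASTA input).
#' @param id genome id; defaults to the LOCUS/FASTA name.
#' @return an [mtgenome].
#' @export
parse_genome <- function(path, format = c("auto", "genbank", "fasta"),
                         feature_table = NULL, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank" else "fasta"
  }
  if (format == "genbank") {
    parse_genbank(path, id = id)
  } else {
    if (is.null(feature_table)) stop("FASTA input requires a feature_table TSV")
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) != 1L) stop("expected exactly one FASTA record in ", path)
    feats <- read.delim(feature_table, stringsAsFactors = FALSE)
    need <- c("label", "kind", "start", "end", "strand")
    if (!all(need %in% names(feats))) {
      stop("feature table must have columns: ", paste(need, collapse = ", "))
    }
    nm <- if (is.null(id)) sub("\\s.*$", "", names(seqs)[1L]) else id
    mtgenome(nm, as.character(seqs[[1L]]), feats)
  }
}

# GenBank feature keys consumed; everything else in FEATURES is ignored.
GBK_KIND <- c(CDS = "PCG", rRNA = "rRNA", tRNA = "tRNA", D_loop = "CR")

parse_genbank <- function(path, id = NULL) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("malformed GenBank file (no LOCUS line): ", path)
  locus_id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(fstart) == 0L || length(ostart) == 0L) {
    stop("malformed GenBank file (missing FEATURES or ORIGIN): ", path)
  }
  # sequence
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  # features
  feat_lines <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
  feats <- list()
  cur <- NULL
  for (k in seq_along(feat_lines)) {
    ln <- feat_lines[k]
    if (grepl("^     \\S", ln)) { # new feature entry
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(parts) < 2L) {
        stop("malformed feature line ", fstart[1L] + k, " in ", path, ": ", ln)
      }
      key <- gsub("-", "_", parts[1L])
      cur <- list(key = key, location = parts[2L], qualifiers = character(0),
                  line = fstart[1L] + k)
    } else if (!is.null(cur)) {
      q <- trimws(ln)
      if (startsWith(q, "/")) {
        cur$qualifiers <- c(cur$qualifiers, q)
      } else {
        cur$location <- paste0(cur$location, q) # continued location
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  rows <- list()
  for (ft in feats) {
    if (!ft$key %in% names(GBK_KIND)) next
    loc <- parse_gbk_location(ft$location)
    if (is.null(loc)) {
      stop("cannot parse location of feature at line ", ft$line, ": ",
           ft$location)
    }
    lab <- gbk_qualifier(ft$qualifiers, "gene")
    if (is.na(lab)) lab <- gbk_qualifier(ft$qualifiers, "product")
    if (is.na(lab) && ft$key == "D_loop") lab <- "CR"
    if (is.na(lab)) {
      stop("feature at line ", ft$line, " has no /gene or /product qualifier")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = lab, kind = unname(GBK_KIND[ft$key]),
      start = loc$start, end = loc$end,
      strand = if (loc$complement) "N" else "J",
      wraps = loc$wraps, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no usable features found in ", path)
  mtgenome(if (is.null(id)) locus_id else id, sequence, do.call(rbind, rows))
}

# supports "a..b", "complement(a..b)", and an origin-spanning
# "join(a..L,1..b)" in either orientation
parse_gbk_location <- function(loc) {
  comp <- grepl("^complement\\(", loc)
  core <- sub("^complement\\((.*)\\)$", "\\1", loc)
  wraps <- FALSE
  if (grepl("^join\\(", core)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", core)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) return(NULL)
    r1 <- parse_gbk_range(parts[1L]); r2 <- parse_gbk_range(parts[2L])
    if (is.null(r1) || is.null(r2)) return(NULL)
    return(list(start = r1[1L], end = r2[2L], complement = comp, wraps = TRUE))
  }
  r <- parse_gbk_range(core)
  if (is.null(r)) return(NULL)
  list(start = r[1L], end = r[2L], complement = comp, wraps = wraps)
}

parse_gbk_range <- function(x) {
  m <- regmatches(x, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", trimws(x)))[[1L]]
  if (length(m) != 3L) return(NULL)
  as.integer(m[2:3])
}

gbk_qualifier <- function(quals, name) {
  pat <- paste0("^/", name, "=\"?([^\"]*)\"?$")
  hit <- grep(pat, quals, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(pat, "\\1", hit[1L])
}

#' Write a genome as GenBank, FASTA and feature TSV
#'
#' Output is deterministic (fixed LOCUS date) so identical genomes round-trip
#' to byte-identical files.
#'
#' @param genome an [mtgenome].
#' @param dir output directory (created if needed).
#' @param name file stem; defaults to the genome id.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir, name = genome$id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- file.path(dir, paste0(name, ".gb"))
  fa <- file.path(dir, paste0(name, ".fasta"))
  tsv <- file.path(dir, paste0(name, ".features.tsv"))
  writeLines(format_genbank(genome), gb)
  writeLines(c(paste0(">", genome$id),
               substring(genome$sequence,
                         seq(1L, genome$length, 70L),
                         pmin(seq(1L, genome$length, 70L) + 69L, genome$length))),
             fa)
  f <- genome$features[, c("label", "kind", "start", "end", "strand", "wraps")]
  write.table(f, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genbank = gb, fasta = fa, features = tsv))
}

format_genbank <- function(genome) {
  key_of <- c(PCG = "CDS", rRNA = "rRNA", tRNA = "tRNA", CR = "D-loop")
  out <- c(sprintf("LOCUS       %s %d bp    DNA     circular INV 01-JAN-2000",
                   genome$id, genome$length),
           sprintf("DEFINITION  %s mitochondrion, complete genome.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", genome$length))
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    loc <- if (f$wraps) {
      sprintf("join(%d..%d,1..%d)", f$start, genome$length, f$end)
    } else {
      sprintf("%d..%d", f$start, f$end)
    }
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-15s %s", key_of[[f$kind]], loc),
             sprintf("                     /gene=\"%s\"", f$label))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, genome$length, 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, genome$length))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  c(out, "//")
}

#' Derive the circular gene order from an annotated genome
#'
#' @param genome an [mtgenome].
#' @param include feature kinds to include.
#' @param origin label used as linearization anchor (default `"CR"`; pass
#'   another label for genomes without an annotated control region).
#' @param short shorten labels to order tokens (`trnI2` -> `I2`)?
#' @return a [gene_order] with strand recorded as sign.
#' @export
extract_gene_order <- function(genome, include = FEATURE_KINDS,
                               origin = "CR", short = TRUE) {
  f <- genome$features[genome$features$kind %in% include, , drop = FALSE]
  if (nrow(f) == 0L) stop("no features of kind(s) ", paste(include, collapse = ","))
  labs <- if (short) short_label(f$label) else f$label
  ord <- gene_order(labs, strands = ifelse(f$strand == "J", 1L, -1L),
                    origin = labs[1L])
  if (short) origin <- short_label(origin)
  if (!origin %in% ord$labels) {
    stop("origin label '", origin, "' absent; available: ",
         paste(ord$labels, collapse = ", "))
  }
  rotate_to(ord, origin)
}

# logical coverage vector of all annotated features on the circle
feature_coverage <- function(genome) {
  cov <- logical(genome$length)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    cov[circular_positions(f$start[i], f$end[i], genome$length)] <- TRUE
  }
  cov
}

#' Non-coding regions (intergenic spacers) of a genome
#'
#' Every position not covered by any annotated feature belongs to exactly one
#' NCR; runs are computed on the circle so a spacer crossing the origin is a
#' single record.
#'
#' @param genome an [mtgenome].
#' @param min_len report only NCRs at least this long (all are counted in the
#'   `total_ncr_bp` attribute regardless).
#' @return data.frame with `start`, `end`, `length`, `flank_left`,
#'   `flank_right` (labels of the abutting features), plus attribute
#'   `total_ncr_bp`.
#' @export
intergenic_regions <- function(genome, min_len = 1L) {
  cov <- feature_coverage(genome)
  len <- genome$length
  total <- sum(!cov)
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      flank_left = character(0), flank_right = character(0),
                      stringsAsFactors = FALSE)
  if (total == 0L) return(structure(empty, total_ncr_bp = 0L))
  r <- rle(!cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge a run touching position len with one starting at 1 (circular wrap)
  if (nrow(runs) > 1L && runs$start[1L] == 1L && runs$end[nrow(runs)] == len) {
    runs$start[1L] <- runs$start[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  f <- genome$features
  flank <- function(pos) {
    # feature covering the given position; prefer the one ending latest
    hit <- which(vapply(seq_len(nrow(f)), function(i) {
      pos %in% circular_positions(f$start[i], f$end[i], len)
    }, logical(1L)))
    if (length(hit) == 0L) return(NA_character_)
    f$label[hit[1L]]
  }
  runs$length <- vapply(seq_len(nrow(runs)),
                        function(i) circular_span(runs$start[i], runs$end[i], len),
                        integer(1L))
  runs$flank_left <- vapply(runs$start,
                            function(s) flank(if (s == 1L) len else s - 1L),
                            character(1L))
  runs$flank_right <- vapply(runs$end,
                             function(e) flank(if (e == len) 1L else e + 1L),
                             character(1L))
  runs <- runs[runs$length >= min_len, , drop = FALSE]
  rownames(runs) <- NULL
  structure(runs, total_ncr_bp = total)
}

#' Pairwise gene overlaps
#'
#' Reports every pair of annotated features whose intervals intersect on the
#' circle, with the overlap length in bp. Circular adjacency is included.
#'
#' @param genome an [mtgenome].
#' @return data.frame with `label_a`, `label_b`, `overlap_bp`.
#' @export
gene_overlaps <- function(genome) {
  f <- genome$features
  n <- nrow(f)
  out <- list()
  pos <- lapply(seq_len(n), function(i) {
    circular_positions(f$start[i], f$end[i], genome$length)
  })
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      ov <- length(intersect(pos[[i]], pos[[j]]))
      if (ov > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          label_a = f$label[i], label_b = f$label[j], overlap_bp = ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(label_a = character(0), label_b = character(0),
                      overlap_bp = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Start/stop codon table for protein-coding genes
#'
#' The start codon is the first strand-corrected triplet. A length remainder
#' of 1 or 2 modulo 3 marks an incomplete stop (a trailing `T` or `TA`,
#' completed to TAA by polyadenylation of the transcript); otherwise the final
#' triplet is reported and checked against the invertebrate-mitochondrial
#' stops TAA/TAG. Starts other than ATN are flagged unconventional (GTG and
#' TTG starts occur in insect mitogenomes).
#'
#' @param genome an [mtgenome].
#' @return data.frame with `label`, `start_codon`, `stop_codon`,
#'   `complete` (logical), `unconventional_start` (logical).
#' @export
codon_boundaries <- function(genome) {
  f <- genome$features[genome$features$kind == "PCG", , drop = FALSE]
  rows <- lapply(seq_len(nrow(f)), function(i) {
    s <- f$sequence[i]
    n <- nchar(s)
    if (n < 6L) stop("PCG '", f$label[i], "' shorter than 6 nt")
    start <- substr(s, 1L, 3L)
    r <- n %% 3L
    if (r == 0L) {
      stop_codon <- substr(s, n - 2L, n)
      complete <- stop_codon %in% c("TAA", "TAG")
    } else {
      stop_codon <- substr(s, n - r + 1L, n)
      complete <- FALSE
    }
    data.frame(label = f$label[i], start_codon = start, stop_codon = stop_codon,
               complete = complete,
               unconventional_start = !grepl("^AT[ACGT]$", start),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-object genome summary
#'
#' Convenience bundle used by the report writers: composition, NCR totals,
#' overlap count and codon boundary table.
#'
#' @param genome an [mtgenome].
#' @return list.
#' @export
genome_summary <- function(genome) {
  ncrs <- intergenic_regions(genome)
  ov <- gene_overlaps(genome)
  list(id = genome$id, length = genome$length,
       n_features = nrow(genome$features),
       n_by_kind = as.list(table(genome$features$kind)),
       total_ncr_bp = attr(ncrs, "total_ncr_bp"),
       # both counting conventions: spacers only, and spacers plus the CR
       # (itself a non-coding feature)
       n_ncr = nrow(ncrs),
       n_ncr_incl_cr = nrow(ncrs) + sum(genome$features$kind == "CR"),
       longest_ncr = if (nrow(ncrs)) max(ncrs$length) else 0L,
       n_overlaps = nrow(ov),
       max_overlap = if (nrow(ov)) max(ov$overlap_bp) else 0L)
}
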