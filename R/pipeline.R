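# End-to-end orchestration: composition -> codon stats -> tRNA analysis ->
# NCR scan -> gene-order comparison -> remold-aware TDRL inference.

# map an annotated feature label to its token in a reference gene order:
# keep it when the reference knows it, otherwise strip a duplicate number
# (I1 -> I; L1 stays L1 because the reference carries it)
map_to_order_token <- function(label, reference_labels) {
  tok <- short_label(label)
  out <- tok
  miss <- !tok %in% reference_labels
  stripped <- sub("[0-9]+$", "", tok[miss])
  out[miss] <- ifelse(stripped %in% reference_labels, stripped, tok[miss])
  out
}

#' Run the full rearrangement analysis on one genome
#'
#' Stages: base composition; codon usage with RSCU and GC-ending ratios;
#' tRNA extraction, cloverleaf validation and remolding detection; NCR
#' inventory, gene overlaps, codon boundaries, pseudogene/G-element/tandem
#' repeat scans; gene-order comparison against a reference; and, when the
#' order differs, TDRL scenario enumeration with remold-informed
#' `allowed_duplicates` and scan-informed observed remnants. A stage failure
#' is recorded in `$errors` and later independent stages still run.
#'
#' @param genome an [mtgenome] or a file path accepted by [parse_genome].
#' @param reference reference (ancestral) gene order; defaults to
#'   [ancestral_gene_order()].
#' @param donor_min_identity,own_max_identity remolding thresholds, see
#'   [detect_remolding].
#' @param min_len,min_identity pseudogene scan thresholds, see
#'   [pseudogene_scan].
#' @param max_window TDRL enumeration window guard.
#' @param stages which stage groups to run: `"stats"` (composition, codon
#'   usage), `"trna"` (tRNA extraction, cloverleaf, remolding), `"scan"`
#'   (NCRs, overlaps, codon boundaries, pseudogene and G-element scans),
#'   `"repeats"` (tandem repeats in the CR), `"tdrl"` (order comparison and
#'   scenario inference; uses the trna and scan results when available).
#' @return list of class `mito_report`.
#' @export
run_pipeline <- function(genome, reference = ancestral_gene_order(),
                         donor_min_identity = 85, own_max_identity = 70,
                         min_len = 20L, min_identity = 70,
                         max_window = 12L,
                         stages = c("stats", "trna", "scan", "repeats",
                                    "tdrl")) {
  if (is.character(genome)) genome <- parse_genome(genome)
  stopifnot(inherits(genome, "mtgenome"))
  errors <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }
  comp <- usage <- NULL
  if ("stats" %in% stages) {
    comp <- stage("composition", composition(genome))
    usage <- stage("codon_usage", codon_usage(genome))
  }
  gc_ratio <- if (!is.null(usage)) stage("gc_ending", gc_ending_ratio(usage))
  trnas <- if ("trna" %in% stages) stage("trna", trna_genes(genome))
  cloverleafs <- if (!is.null(trnas)) {
    stage("cloverleaf", lapply(seq_len(nrow(trnas)), function(i) {
      if (is.na(trnas$anticodon_offset[i])) return(NULL)
      cloverleaf_validate(trnas$sequence[i],
                          anticodon_offset = trnas$anticodon_offset[i])
    }))
  }
  remolds <- if (!is.null(trnas) && nrow(trnas) >= 2L) {
    stage("remolding", detect_remolding(trnas, donor_min_identity,
                                        own_max_identity))
  }
  ncrs <- overlaps <- boundaries <- pseudo <- NULL
  cr_row <- which(genome$features$kind == "CR")
  g_elements <- repeats <- NULL
  if ("scan" %in% stages) {
    ncrs <- stage("ncr", intergenic_regions(genome))
    overlaps <- stage("overlaps", gene_overlaps(genome))
    boundaries <- stage("codon_boundaries", codon_boundaries(genome))
    pseudo <- stage("pseudogene_scan",
                    pseudogene_scan(genome, min_len = min_len,
                                    min_identity = min_identity))
    if (length(cr_row)) {
      cr_seq <- genome$features$sequence[cr_row[1L]]
      g_elements <- stage("g_element", g_element_scan(cr_seq))
      if ("repeats" %in% stages) {
        repeats <- stage("tandem_repeats", tandem_repeat_scan(cr_seq))
      }
    }
  }
  observed_order <- if ("tdrl" %in% stages) {
    stage("gene_order", extract_gene_order(
      genome, origin = if (length(cr_row)) "CR" else genome$features$label[1L]))
  }

  rearranged <- NA
  scenarios <- list()
  top_scenario <- NULL
  observed_remnants <- NULL
  if (!is.null(observed_order)) {
    rearranged <- !order_equal(observed_order, reference)
    if (isTRUE(rearranged)) {
      remold_map <- NULL
      allowed <- character(0)
      if (!is.null(remolds) && nrow(remolds) > 0L) {
        remold_map <- setNames(short_label(remolds$donor),
                               short_label(remolds$label))
        allowed <- unique(short_label(remolds$donor))
      }
      if (!is.null(pseudo) && nrow(pseudo) > 0L) {
        evidence <- filter_dominant_hits(pseudo)
        observed_remnants <- data.frame(
          donor = map_to_order_token(evidence$donor, reference$labels),
          left = short_label(evidence$flank_left),
          right = short_label(evidence$flank_right),
          stringsAsFactors = FALSE)
        observed_remnants <-
          observed_remnants[!duplicated(observed_remnants), , drop = FALSE]
      }
      scenarios <- stage("tdrl", enumerate_single_tdrl(
        reference, observed_order, allowed_duplicates = allowed,
        remold_map = remold_map, max_window = max_window))
      if (is.null(scenarios)) scenarios <- list()
      if (length(scenarios)) {
        scenarios <- rank_scenarios(scenarios, observed_remnants)
        top_scenario <- scenarios[[1L]]
      }
    }
  }
  structure(list(
    id = genome$id,
    summary = genome_summary(genome),
    composition = comp,
    codon_usage = usage,
    top_codons = if (!is.null(usage)) top_codons(usage),
    gc_ending = gc_ratio,
    trnas = trnas,
    cloverleafs = cloverleafs,
    remolds = remolds,
    ncrs = ncrs,
    overlaps = overlaps,
    codon_boundaries = boundaries,
    pseudo_hits = pseudo,
    g_elements = g_elements,
    tandem_repeats = repeats,
    gene_order = observed_order,
    reference = reference,
    rearranged = rearranged,
    observed_remnants = observed_remnants,
    scenarios = scenarios,
    top_scenario = top_scenario,
    errors = errors), class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat("== mito_report:", x$id, "==\n")
  cat(sprintf("genome %d bp, %d features, %d bp NCR, %d overlaps\n",
              x$summary$length, x$summary$n_features, x$summary$total_ncr_bp,
              x$summary$n_overlaps))
  if (!is.null(x$composition)) {
    cat(sprintf("AT %.1f%%, AT-skew %.2f, GC-skew %.2f\n",
                x$composition$at_content, x$composition$at_skew,
                x$composition$gc_skew))
  }
  if (!is.null(x$remolds) && nrow(x$remolds)) {
    cat("remold calls:", paste(x$remolds$label, "<-", x$remolds$donor,
                               collapse = "; "), "\n")
  }
  if (isTRUE(x$rearranged)) {
    cat("gene order differs from the reference;",
        length(x$scenarios), "single-TDRL scenario(s)\n")
    if (!is.null(x$top_scenario)) {
      cat("top scenario: duplicate [",
          paste(x$top_scenario$block_labels, collapse = "-"),
          "], matched ", x$top_scenario$matched, " remnant(s)\n", sep = "")
    }
  } else if (identical(x$rearranged, FALSE)) {
    cat("no rearrangement detected (order matches the reference)\n")
  }
  if (length(x$errors)) cat("stage errors:", paste(x$errors, collapse = "; "),
                            "\n")
  invisible(x)
}

#' Write a consolidated report bundle
#'
#' JSON summary (stable key order) plus TSV tables for the feature-level
#' results.
#'
#' @param report a `mito_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  js <- list(
    id = report$id,
    summary = report$summary,
    composition = if (!is.null(report$composition)) list(
      pct = as.list(report$composition$pct),
      at_content = report$composition$at_content,
      at_skew = report$composition$at_skew,
      gc_skew = report$composition$gc_skew),
    top_codons = report$top_codons,
    remolds = report$remolds,
    rearranged = report$rearranged,
    gene_order = if (!is.null(report$gene_order))
      signed_labels(report$gene_order),
    n_scenarios = length(report$scenarios),
    top_scenario = if (!is.null(report$top_scenario)) list(
      block = report$top_scenario$block_labels,
      fates = report$top_scenario$event$fates,
      losses = report$top_scenario$losses,
      matched = report$top_scenario$matched,
      unmatched_predictions = report$top_scenario$unmatched,
      remolds = report$top_scenario$remolds),
    errors = report$errors)
  jp <- file.path(dir, paste0(report$id, ".report.json"))
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  paths <- c(paths, jp)
  tables <- list(codon_usage = report$codon_usage, ncrs = report$ncrs,
                 overlaps = report$overlaps,
                 codon_boundaries = report$codon_boundaries,
                 pseudo_hits = report$pseudo_hits)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    tp <- file.path(dir, paste0(report$id, ".", nm, ".tsv"))
    write.table(tables[[nm]], tp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Headline quantities recomputed from a reference-accession record
#'
#' Given a locally stored annotated GenBank record of the focal assassin-bug
#' mitogenome, recomputes the quantities the analysis reports for it: genome
#' length, coding gene count, NCR totals, overlap count, isoleucine codon
#' total, the mismatch count between the remolded Ile tRNA and its Met
#' donor, and the pseudo-ND2/pseudo-CR remnant statistics.
#'
#' @param path GenBank file of the record.
#' @return list of the recomputed quantities.
#' @export
accession_report <- function(path) {
  g <- parse_genome(path)
  ncrs <- intergenic_regions(g)
  ov <- gene_overlaps(g)
  usage <- codon_usage(g)
  ile <- sum(usage$count[usage$codon %in% c("ATT", "ATC")])
  trnas <- trna_genes(g)
  i2 <- grep("^trnI2$", trnas$label)
  m <- grep("^trnM$", trnas$label)
  i2_vs_m <- if (length(i2) && length(m)) {
    pairwise_identity(trnas$sequence[i2], trnas$sequence[m])$mismatches
  } else NA_integer_
  pseudo <- pseudogene_scan(g)
  pick <- function(donor) {
    h <- pseudo[pseudo$donor == donor & !(pseudo$flank_left == donor |
                                            pseudo$flank_right == donor), ,
                drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    h[which.max(h$length), , drop = FALSE]
  }
  nd2 <- pick("ND2")
  crh <- pick("CR")
  list(genome_length = g$length,
       n_coding_genes = sum(g$features$kind != "CR"),
       total_ncr_bp = attr(ncrs, "total_ncr_bp"),
       n_overlaps = nrow(ov),
       max_overlap = if (nrow(ov)) max(ov$overlap_bp) else 0L,
       ile_codons = ile,
       trnI2_trnM_mismatches = i2_vs_m,
       psi_nd2_length = if (!is.null(nd2)) nd2$length else NA_integer_,
       psi_nd2_identity = if (!is.null(nd2)) nd2$identity else NA_real_,
       psi_cr_length = if (!is.null(crh)) crh$length else NA_integer_,
       psi_cr_mismatches = if (!is.null(crh)) crh$mismatches else NA_integer_)
}
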