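# Bundled reference tables: the 22 metazoan mitochondrial tRNA anticodon
# families (DNA spelling) and the ancestral insect gene order.

#' Anticodon-to-family table for the invertebrate mitochondrial code
#'
#' The 22 tRNA families found in insect mitochondrial genomes, keyed by the
#' anticodon in DNA spelling (5'->3'). Leucine and serine are split into the
#' two-gene families L1 (CUN codons), L2 (UUR), S1 (AGN) and S2 (UCN).
#'
#' @return named character vector: anticodon -> family label.
#' @export
anticodon_table <- function() {
  c(TGC = "A",  TCG = "R",  GTT = "N",  GTC = "D",  GCA = "C",
    TTG = "Q",  TTC = "E",  TCC = "G",  GTG = "H",  GAT = "I",
    TTT = "K",  TAG = "L1", TAA = "L2", CAT = "M",  GAA = "F",
    TGG = "P",  GCT = "S1", TGA = "S2", TGT = "T",  TCA = "W",
    GTA = "Y",  TAC = "V")
}

#' Map a tRNA family label to its canonical anticodon
#' @param family family label as in [anticodon_table()] (e.g. "M", "I", "L1").
#' @return 3-nt DNA anticodon.
#' @export
family_anticodon <- function(family) {
  tab <- anticodon_table()
  out <- setNames(names(tab), tab)[family]
  unname(out)
}

#' Assign the amino-acid family implied by an anticodon
#'
#' Looks the anticodon up in the bundled invertebrate-mitochondrial table.
#' An anticodon absent from the table yields `NA` with a warning (it may be a
#' sequencing or annotation artefact rather than a real decoding identity).
#'
#' @param anticodon 3-nt DNA string over A/C/G/T.
#' @return family label (character) or `NA`.
#' @export
anticodon_family <- function(anticodon) {
  stopifnot(is.character(anticodon), length(anticodon) == 1L)
  anticodon <- toupper(anticodon)
  if (!grepl("^[ACGT]{3}$", anticodon)) {
    stop("anticodon must be a 3-nt DNA string over A/C/G/T, got: ", anticodon)
  }
  fam <- anticodon_table()[anticodon]
  if (is.na(fam)) {
    warning("unknown anticodon: ", anticodon)
    return(NA_character_)
  }
  unname(fam)
}

# roster of the 37 typical insect mt genes + CR, in the ancestral order
# (linearized at the control region). strand +1 = majority (J), -1 = minority.
ANCESTRAL_ROSTER <- data.frame(
  label = c("CR", "trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY",
            "COI", "trnL2", "COII", "trnK", "trnD", "ATP8", "ATP6", "COIII",
            "trnG", "ND3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF",
            "ND5", "trnH", "ND4", "ND4L", "trnT", "trnP", "ND6", "CytB",
            "trnS2", "ND1", "trnL1", "lrRNA", "trnV", "srRNA"),
  kind = c("CR", "tRNA", "tRNA", "tRNA", "PCG", "tRNA", "tRNA", "tRNA",
           "PCG", "tRNA", "PCG", "tRNA", "tRNA", "PCG", "PCG", "PCG",
           "tRNA", "PCG", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA",
           "PCG", "tRNA", "PCG", "PCG", "tRNA", "tRNA", "PCG", "PCG",
           "tRNA", "PCG", "tRNA", "rRNA", "tRNA", "rRNA"),
  strand = c(1L, 1L, -1L, 1L, 1L, 1L, -1L, -1L,
             1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
             1L, 1L, 1L, 1L, 1L, 1L, 1L, -1L,
             -1L, -1L, -1L, -1L, 1L, -1L, 1L, 1L,
             1L, -1L, -1L, -1L, -1L, -1L),
  length = c(1251L, 69L, 69L, 69L, 1002L, 69L, 69L, 69L,
             1536L, 69L, 684L, 69L, 69L, 156L, 675L, 789L,
             69L, 354L, 69L, 69L, 69L, 69L, 69L, 69L,
             1716L, 69L, 1332L, 291L, 69L, 69L, 456L, 1137L,
             69L, 924L, 69L, 1255L, 69L, 784L),
  stringsAsFactors = FALSE
)

#' The ancestral insect mitochondrial gene order
#'
#' The gene arrangement shared by most insects (the *Drosophila yakuba*
#' pattern), as a [gene_order] linearized at the control region. Used as the
#' default reference when comparing observed orders.
#'
#' @return a `gene_order`.
#' @export
ancestral_gene_order <- function() {
  gene_order(short_label(ANCESTRAL_ROSTER$label),
             strands = ANCESTRAL_ROSTER$strand, origin = "CR")
}

#' Shorten feature labels to order tokens
#'
#' tRNA labels lose their `trn` prefix (`trnI2` -> `I2`); all other labels
#' (PCGs, rRNAs, CR) are kept as-is.
#'
#' @param label character vector of feature labels.
#' @return character vector of order tokens.
#' @export
short_label <- function(label) sub("^trn", "", label)
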