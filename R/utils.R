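# Small sequence helpers shared across modules. Sequences are plain upper-case
# DNA character scalars throughout; Biostrings objects are built only at I/O
# boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Ambiguity codes other than N are left untouched by complementation only for
#' the IUPAC subset handled by [chartr()]; N maps to N.
#'
#' @param x character scalar, DNA.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  comp <- chartr("ACGTNRYKMBDHVacgtn", "TGCANYRMKVHDBtgcan", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# split a DNA scalar into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# random DNA of length n with a target AT fraction (A/T and G/C split evenly)
random_dna <- function(n, at = 0.672) {
  if (n <= 0L) return("")
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Watson-Crick or G.T wobble pair (DNA alphabet)
is_wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

# positions (1-based) covered by a possibly origin-wrapping interval on a
# circle of size len
circular_positions <- function(start, end, len) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, len), seq.int(1L, end))
}

circular_span <- function(start, end, len) {
  if (start <= end) end - start + 1L else len - start + 1L + end
}
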