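# Circular signed gene orders: the unit of rearrangement analysis.

#' Construct a circular gene order
#'
#' A gene order is a circular list of gene labels with a strand sign per gene
#' (+1 majority/J strand, -1 minority/N strand) and a linearization anchor.
#' Equality between orders is rotation-invariant and sign-aware.
#'
#' @param labels character vector of gene labels; a leading `-` on a label is
#'   parsed as a minus strand (e.g. `"-Q"`).
#' @param strands integer vector of +1/-1, recycled; ignored for labels that
#'   carry an explicit `-` prefix.
#' @param origin label used as linearization anchor (default first label, or
#'   `"CR"` when present).
#' @return object of class `gene_order`.
#' @export
gene_order <- function(labels, strands = NULL, origin = NULL) {
  stopifnot(is.character(labels), length(labels) > 0L, all(nzchar(labels)))
  neg <- startsWith(labels, "-")
  lab <- ifelse(neg, substring(labels, 2L), labels)
  if (is.null(strands)) strands <- rep(1L, length(lab))
  strands <- rep_len(as.integer(strands), length(lab))
  strands[neg] <- -1L
  if (is.null(origin)) origin <- if ("CR" %in% lab) "CR" else lab[1L]
  if (!origin %in% lab) {
    stop("origin label '", origin, "' not in order; available: ",
         paste(unique(lab), collapse = ", "))
  }
  structure(list(labels = lab, strands = strands, origin = origin),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> (circular, anchored at ", x$origin, ")\n  ",
      paste(signed_labels(x), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$labels)

#' Signed label representation of a gene order
#' @param order a `gene_order`.
#' @return character vector with `-` prefixes on minus-strand genes.
#' @export
signed_labels <- function(order) {
  ifelse(order$strands < 0L, paste0("-", order$labels), order$labels)
}

#' Rotate a gene order so a given label comes first
#'
#' @param order a `gene_order`.
#' @param label label to rotate to (first occurrence).
#' @return rotated `gene_order` with `label` as the new origin.
#' @export
rotate_to <- function(order, label) {
  i <- match(label, order$labels)
  if (is.na(i)) {
    stop("label '", label, "' not in order; available: ",
         paste(unique(order$labels), collapse = ", "))
  }
  n <- length(order$labels)
  idx <- if (i == 1L) seq_len(n) else c(i:n, seq_len(i - 1L))
  gene_order(order$labels[idx], order$strands[idx], origin = label)
}

#' Rotation-invariant equality of circular gene orders
#'
#' Two orders are equal when some rotation aligns both labels and strand
#' signs. Reflections (whole-molecule flips) are not considered.
#'
#' @param a,b `gene_order` objects.
#' @return logical.
#' @export
order_equal <- function(a, b) {
  if (length(a$labels) != length(b$labels)) return(FALSE)
  n <- length(a$labels)
  sa <- signed_labels(a)
  sb <- signed_labels(b)
  for (k in seq_len(n)) {
    idx <- c(k:n, seq_len(k - 1L))[seq_len(n)]
    if (identical(sb[idx], sa)) return(TRUE)
  }
  FALSE
}

#' Read gene orders from the plain-text order format
#'
#' One circular genome per line of comma-separated signed labels, preceded by
#' a `>`-prefixed name line (FASTA-like).
#'
#' @param path file path.
#' @return named list of `gene_order` objects.
#' @export
read_gene_orders <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  name <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      name <- trimws(substring(ln, 2L))
    } else {
      labs <- trimws(strsplit(ln, ",", fixed = TRUE)[[1L]])
      if (is.null(name)) name <- paste0("order", length(out) + 1L)
      out[[name]] <- gene_order(labs)
      name <- NULL
    }
  }
  out
}

#' Write gene orders in the plain-text order format
#' @param orders named list of `gene_order` objects.
#' @param path file path.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- character(0)
  nms <- names(orders)
  for (i in seq_along(orders)) {
    lines <- c(lines, paste0(">", nms[i]),
               paste(signed_labels(orders[[i]]), collapse = ","))
  }
  writeLines(lines, path)
}
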