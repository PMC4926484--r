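# User-facing wrappers over the compiled alignment kernels.

#' Pairwise sequence identity
#'
#' Global mode aligns the two sequences with Needleman-Wunsch (match +1,
#' mismatch -1, gap -2 by default) and reports identity as matches over
#' aligned columns (gap columns included in the denominator). The mismatch
#' count excludes gap columns and is reported separately. Ambiguity codes
#' count as neither match nor mismatch. Ungapped mode compares two
#' equal-length sequences position by position.
#'
#' @param a,b DNA character scalars.
#' @param mode `"global"` or `"ungapped"`.
#' @param match,mismatch,gap scoring (global mode).
#' @return list: `identity` (percent), `mismatches`, `alignment_length`,
#'   `matches`, `score`, `aligned_a`, `aligned_b`.
#' @export
pairwise_identity <- function(a, b, mode = c("global", "ungapped"),
                              match = 1, mismatch = -1, gap = -2) {
  mode <- match.arg(mode)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  a <- toupper(a); b <- toupper(b)
  if (mode == "global") {
    al <- .nw_align_cpp(a, b, match, mismatch, gap)
    list(identity = 100 * al$matches / al$columns,
         mismatches = al$mismatches, alignment_length = al$columns,
         matches = al$matches, score = al$score,
         aligned_a = al$aligned_a, aligned_b = al$aligned_b)
  } else {
    if (nchar(a) != nchar(b)) {
      stop("ungapped mode requires equal-length sequences")
    }
    ca <- seq_chars(a); cb <- seq_chars(b)
    plain <- ca %in% DNA_BASES & cb %in% DNA_BASES
    matches <- sum(plain & ca == cb)
    mismatches <- sum(plain & ca != cb)
    list(identity = 100 * matches / nchar(a), mismatches = mismatches,
         alignment_length = nchar(a), matches = matches,
         score = matches * match + mismatches * mismatch,
         aligned_a = a, aligned_b = b)
  }
}

#' Best local alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under affine-gap scoring; a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Deterministic tie-break: highest score,
#' then smallest end coordinates, with traceback preferring the shortest
#' alignment and diagonal moves, which keeps reported hits stable across
#' runs.
#'
#' @param query,target DNA character scalars.
#' @param scoring named numeric vector `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (penalties negative).
#' @return list: `score`, `identity` (percent of aligned columns), `length`
#'   (aligned columns), `matches`, `mismatches`, `q_start`, `q_end`,
#'   `t_start`, `t_end`, `aligned_q`, `aligned_t`. A sequence pair with no
#'   positive-scoring alignment returns `score = 0` and `length = 0`.
#' @export
smith_waterman <- function(query, target,
                           scoring = c(match = 1, mismatch = -1,
                                       gap_open = -2, gap_extend = -1)) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  al <- .sw_align_cpp(toupper(query), toupper(target),
                      scoring[["match"]], scoring[["mismatch"]],
                      scoring[["gap_open"]], scoring[["gap_extend"]])
  if (isTRUE(al$empty)) {
    return(list(score = 0, identity = NA_real_, length = 0L,
                matches = 0L, mismatches = 0L,
                q_start = NA_integer_, q_end = NA_integer_,
                t_start = NA_integer_, t_end = NA_integer_,
                aligned_q = "", aligned_t = ""))
  }
  list(score = al$score,
       identity = 100 * al$matches / al$columns,
       length = al$columns, matches = al$matches, mismatches = al$mismatches,
       q_start = al$q_start, q_end = al$q_end,
       t_start = al$t_start, t_end = al$t_end,
       aligned_q = al$aligned_q, aligned_t = al$aligned_t)
}
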