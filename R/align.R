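#' Wraparound alignment of a segment against a tandem monomer
#'
#' Aligns a genomic segment against an unbounded head-to-tail concatenation
#' of a monomer (the scoring model of tandem-repeat finding): after the last
#' monomer column the alignment re-enters column 1, and the entry/exit
#' columns are free while the whole segment must be consumed. The score is
#' `match * matches - mismatch * mismatches - indel * indels`, maximized
#' over all such alignments; counts come from one optimal traceback.
#'
#' `N` bases never match (they are scored as mismatches when aligned).
#' Memory is O(length(segment) * length(monomer)) for the traceback matrix.
#'
#' @param segment Uppercase A/C/G/T/N segment string.
#' @param monomer Uppercase A/C/G/T/N monomer string.
#' @param weights [alignment_weights()].
#' @return A list with `score`, `matches`, `mismatches`, `indels` and
#'   `copy_number` (aligned monomer columns consumed divided by the period,
#'   reported to one decimal).
#' @export
#' @examples
#' wraparound_align(strrep("ACGT", 10), "ACGT")$score   # 2 * 40 = 80
wraparound_align <- function(segment, monomer, weights = alignment_weights()) {
  .check_dna(segment, "segment")
  .check_dna(monomer, "monomer")
  stopifnot(inherits(weights, "alignment_weights"))
  res <- wrap_align_cpp(segment, monomer,
                        weights$match, weights$mismatch, weights$indel)
  p <- nchar(monomer)
  list(score = res$score,
       matches = res$matches,
       mismatches = res$mismatches,
       indels = res$indels,
       copy_number = .round_half_up(res$consumed / p, 1L))
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with unit weights (+1 match, -1
#' mismatch, -1 gap, end gaps penalized), maximizing the pair
#' (score, matches) lexicographically; identity is 100 x matches /
#' alignment columns. With unit weights every such optimal alignment has
#' `columns = 2 * matches - score`, so the identity is independent of the
#' traceback and symmetric in its arguments. With
#' `consider_reverse_complement` the better of the two orientations of `b`
#' is returned; with `consider_rotations` the maximum over all cyclic
#' rotations of the shorter sequence is taken (tandem monomers are phase
#' ambiguous).
#'
#' @param a,b Non-empty A/C/G/T/N strings.
#' @param params [cluster_params()] (orientation/rotation flags).
#' @return Identity percent (numeric scalar).
#' @export
#' @examples
#' global_identity("ACGT", "ACGA")  # 75
global_identity <- function(a, b, params = cluster_params()) {
  .check_dna(a, "a")
  .check_dna(b, "b")
  stopifnot(inherits(params, "cluster_params"))
  candidates_b <- b
  if (params$consider_reverse_complement)
    candidates_b <- c(candidates_b, .revcomp(b))
  best <- -Inf
  for (bb in candidates_b) {
    if (params$consider_rotations) {
      if (nchar(a) <= nchar(bb)) {
        rots <- .rotations(a)
        best <- max(best, vapply(rots, function(r)
          nw_identity_cpp(r, bb)[["identity"]], numeric(1L)))
      } else {
        rots <- .rotations(bb)
        best <- max(best, vapply(rots, function(r)
          nw_identity_cpp(a, r)[["identity"]], numeric(1L)))
      }
    } else {
      best <- max(best, nw_identity_cpp(a, bb)[["identity"]])
    }
  }
  best
}

.rotations <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(x)
  doubled <- paste0(x, x)
  vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L),
         character(1L))
}
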