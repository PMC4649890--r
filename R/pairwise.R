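#' k-mer similarity between two sequences
#'
#' Fractional common k-mer count:
#' `sum_tau min(n_i(tau), n_j(tau)) / (min(l_i, l_j) - k + 1)`, where
#' `n_i(tau)` is the occurrence count of k-mer `tau` in sequence `i`.
#' k-mers containing non-ACGT characters are excluded from the profiles.
#' Used to rank clustering candidates cheaply before alignment.
#'
#' @param seq_i,seq_j DNA strings.
#' @param k word length (default 8).
#' @return a similarity in `[0, 1]`; 0 (with a warning) when either
#'   sequence is shorter than `k`.
#' @export
kmer_similarity <- function(seq_i, seq_j, k = 8L) {
  if (nchar(seq_i) < k || nchar(seq_j) < k) {
    warning("sequence shorter than k = ", k, "; similarity defined as 0")
    return(0)
  }
  kmer_similarity_cpp(toupper(seq_i), toupper(seq_j), as.integer(k))
}

#' Global (Needleman-Wunsch) alignment with unit penalties
#'
#' Minimises `mismatch columns + gap columns` (match 0, linear gaps).
#' Among cost-optimal alignments the traceback prefers diagonal moves over
#' gaps in `seq_j` over gaps in `seq_i`, so the result is deterministic.
#' `N` matches nothing, including another `N`. The optimal cost equals the
#' unit-cost edit (Levenshtein) distance of the two strings.
#'
#' @param seq_i,seq_j non-empty DNA strings.
#' @param band optional band half-width (0 = exact, unbanded).
#' @return a `global_alignment` list: `aligned_i`, `aligned_j` (equal
#'   length gapped strings), `cost`, `matches`, `mismatches`,
#'   `gap_columns`.
#' @export
global_align <- function(seq_i, seq_j, band = 0L) {
  stopifnot(nchar(seq_i) > 0, nchar(seq_j) > 0)
  aln <- nw_align_cpp(toupper(seq_i), toupper(seq_j), as.integer(band))
  structure(aln, class = "global_alignment")
}

#' Gap-ignoring pairwise identity
#'
#' Identity is computed only over alignment columns where neither sequence
#' has a gap: `matches / (matches + mismatches)`. Internal and terminal
#' gap columns are ignored, so length differences and indels carry no
#' direct penalty. When no gapless column exists the identity is 0.
#'
#' @param aln a [global_align()] result.
#' @return a fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(aln) {
  denom <- aln$matches + aln$mismatches
  if (denom == 0) return(0)
  aln$matches / denom
}

#' @export
print.global_alignment <- function(x, ...) {
  cat("global alignment  cost:", x$cost, " matches:", x$matches,
      " mismatches:", x$mismatches, " gap columns:", x$gap_columns, "\n")
  cat(x$aligned_i, "\n")
  cat(x$aligned_j, "\n")
  invisible(x)
}
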