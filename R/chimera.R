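#' Simplified de novo bimera detection
#'
#' A transparent two-parent model standing in for full-featured chimera
#' detectors. Queries are taken in increasing abundance order; candidate
#' parents are unflagged dereplicated sequences with abundance at least
#' `min_parent_fold` times the query abundance. The candidate set is
#' pruned to the `max_parents` highest k-mer similarities; each candidate
#' is globally aligned to the query once and its match/mismatch columns
#' are projected onto query coordinates, so every breakpoint of every
#' ordered parent pair can be scored from cumulative sums. The model
#' identity of pair (A, B) at breakpoint b combines the gap-ignoring
#' identity of the query prefix (through b) against A with that of the
#' suffix against B. A query is flagged chimeric when the best model
#' identity reaches `min_model_identity` and exceeds the best
#' single-parent identity by at least `min_gain`.
#'
#' The most abundant sequence can never be flagged (it has no eligible
#' parents). Flagged sequences are excluded as parents for
#' later (more abundant) queries.
#'
#' @param dereps a `derep_set` (re-sorted to decreasing abundance
#'   defensively; results are returned in the input row order).
#' @param min_model_identity minimum two-parent model identity
#'   (default 0.99).
#' @param min_gain minimum improvement over the best single parent
#'   (default 0.02).
#' @param min_parent_fold minimum parent/query abundance ratio
#'   (default 2).
#' @param max_parents number of k-mer-ranked candidate parents aligned
#'   per query (default 8).
#' @param k word length for parent ranking (default 8).
#' @return a data frame of chimera calls: `query_id`, `is_chimera`,
#'   `parent_a`, `parent_b`, `breakpoint`, `model_identity`,
#'   `best_single_identity`, one row per derep in the input row order.
#' @export
detect_chimeras <- function(dereps, min_model_identity = 0.99,
                            min_gain = 0.02, min_parent_fold = 2.0,
                            max_parents = 8L, k = 8L) {
  n <- nrow(dereps)
  if (!n) {
    return(data.frame(query_id = character(), is_chimera = logical(),
                      parent_a = character(), parent_b = character(),
                      breakpoint = integer(), model_identity = numeric(),
                      best_single_identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order_dereps(dereps)
  srt <- dereps[ord, , drop = FALSE]
  res <- chimera_scan_cpp(srt$seq, srt$abundance, min_model_identity,
                          min_gain, min_parent_fold,
                          as.integer(max_parents), as.integer(k))
  calls_srt <- data.frame(
    query_id = srt$rep_id,
    is_chimera = res$is_chimera,
    parent_a = ifelse(is.na(res$parent_a), NA_character_,
                      srt$rep_id[res$parent_a]),
    parent_b = ifelse(is.na(res$parent_b), NA_character_,
                      srt$rep_id[res$parent_b]),
    breakpoint = res$breakpoint,
    model_identity = res$model_identity,
    best_single_identity = res$best_single_identity,
    stringsAsFactors = FALSE)
  out <- calls_srt[order(ord), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply chimera calls to a dereplicated set
#'
#' @param dereps a `derep_set`.
#' @param calls a [detect_chimeras()] result for the same rows.
#' @return `dereps` with the `chimeric` flag set from `calls`.
#' @export
flag_chimeras <- function(dereps, calls) {
  stopifnot(nrow(dereps) == nrow(calls),
            identical(dereps$rep_id, calls$query_id))
  dereps$chimeric <- calls$is_chimera
  dereps
}
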