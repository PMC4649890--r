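#' Clustering parameters
#'
#' @param identity_threshold minimum gap-ignoring pairwise identity for
#'   cluster membership (default 0.97).
#' @param reject_limit reject counter `m`: each candidate scan stops after
#'   `m + 1` consecutive below-threshold alignments (default 32; `Inf`
#'   disables the early stop).
#' @param k word length for the k-mer candidate ranking (default 8).
#' @param derep_mode `"full"` (100% identity clustering) or `"prefix"`
#'   (exact prefix matching) dereplication.
#' @param chimera_filter drop chimera-flagged dereplicated sequences
#'   before clustering (default `TRUE`).
#' @param band optional alignment band half-width (0 = exact).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(identity_threshold = 0.97, reject_limit = 32,
                           k = 8L, derep_mode = c("full", "prefix"),
                           chimera_filter = TRUE, band = 0L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            reject_limit >= 0, k >= 1)
  structure(list(identity_threshold = identity_threshold,
                 reject_limit = reject_limit, k = as.integer(k),
                 derep_mode = match.arg(derep_mode),
                 chimera_filter = isTRUE(chimera_filter),
                 band = as.integer(band)),
            class = "cluster_params")
}

# canonical ordering used everywhere ties arise: abundance desc, length
# desc, sequence ascending byte order (C locale via radix sort)
order_dereps <- function(dereps) {
  order(-dereps$abundance, -nchar(dereps$seq), dereps$seq, method = "radix")
}

new_derep_set <- function(rep_id, seq, abundance, member_ids,
                          member_samples, chimeric = FALSE) {
  df <- data.frame(rep_id = unname(rep_id), seq = unname(seq),
                   abundance = as.integer(unname(abundance)),
                   chimeric = rep_len(chimeric, length(seq)),
                   stringsAsFactors = FALSE)
  df$member_ids <- lapply(unname(member_ids), unname)
  df$member_samples <- lapply(unname(member_samples), unname)
  class(df) <- c("derep_set", "data.frame")
  df
}

# collapse byte-identical sequences; rows ordered canonically
collapse_exact <- function(recs) {
  grp <- split(seq_len(nrow(recs)), recs$seq)
  seqs <- names(grp)
  first <- vapply(grp, `[`, integer(1L), 1L)
  df <- new_derep_set(rep_id = recs$read_id[first], seq = seqs,
                      abundance = lengths(grp),
                      member_ids = lapply(grp, function(i) recs$read_id[i]),
                      member_samples = lapply(grp,
                                              function(i) recs$sample[i]))
  df[order_dereps(df), , drop = FALSE]
}

#' Dereplicate reads
#'
#' `"full"` mode collapses byte-identical reads and then runs the greedy
#' clustering engine at an identity threshold of 1.0, so reads differing
#' only by indels (which the gap-ignoring identity does not penalise,
#' e.g. homopolymer length errors and shorter prefix reads) also merge.
#' `"prefix"` mode is the fast approximation: reads are grouped when they
#' are exact prefixes of the group's longest sequence.
#'
#' Abundance is the number of member reads; the representative id is the
#' first member read id.
#'
#' @param recs a record data frame (see [read_seqs()]).
#' @param mode `"full"` or `"prefix"`.
#' @param params a [cluster_params()] object (supplies `reject_limit`,
#'   `k`, `band` for full mode).
#' @return a `derep_set` data frame (columns `rep_id`, `seq`, `abundance`,
#'   `chimeric`, list-columns `member_ids`, `member_samples`), sorted by
#'   decreasing abundance (ties: length desc, sequence asc).
#' @export
dereplicate <- function(recs, mode = c("full", "prefix"),
                        params = cluster_params()) {
  mode <- match.arg(mode)
  if (!nrow(recs)) {
    return(new_derep_set(character(), character(), integer(), list(),
                         list()))
  }
  uniq <- collapse_exact(recs)
  if (mode == "prefix") {
    ord <- order(-nchar(uniq$seq), -uniq$abundance, uniq$seq,
                 method = "radix")
    uniq <- uniq[ord, , drop = FALSE]
    reps <- integer(0)  # row indices of group representatives
    grp_of <- integer(nrow(uniq))
    for (i in seq_len(nrow(uniq))) {
      hit <- 0L
      if (length(reps)) {
        pref <- startsWith(uniq$seq[reps], uniq$seq[i])
        if (any(pref)) hit <- reps[which(pref)[1L]]
      }
      if (hit) grp_of[i] <- hit
      else { reps <- c(reps, i); grp_of[i] <- i }
    }
    groups <- split(seq_len(nrow(uniq)), grp_of)
    merged <- merge_derep_groups(uniq, groups,
                                 rep_rows = as.integer(names(groups)))
  } else {
    res <- cluster_greedy_cpp(uniq$seq, uniq$abundance, s_thr = 1.0,
                              m = params$reject_limit, k = params$k,
                              band = params$band)
    groups <- lapply(res$members, identity)
    merged <- merge_derep_groups(uniq, groups, rep_rows = res$centroids)
  }
  merged[order_dereps(merged), , drop = FALSE]
}

# combine groups of rows of a derep_set into single entries; the
# representative row supplies seq and rep_id
merge_derep_groups <- function(uniq, groups, rep_rows) {
  rep_rows <- as.integer(rep_rows)
  new_derep_set(
    rep_id = uniq$rep_id[rep_rows],
    seq = uniq$seq[rep_rows],
    abundance = vapply(groups, function(g) sum(uniq$abundance[g]),
                       integer(1L)),
    member_ids = lapply(groups,
                        function(g) unlist(uniq$member_ids[g],
                                           use.names = FALSE)),
    member_samples = lapply(groups,
                            function(g) unlist(uniq$member_samples[g],
                                               use.names = FALSE)))
}

#' Greedy candidate search for one seed
#'
#' The database is ranked by decreasing k-mer similarity to the seed
#' (ties: abundance desc, length desc, sequence asc) and scanned in order;
#' targets with gap-ignoring identity at or above the threshold are
#' accepted (resetting the reject counter), others increment it; the scan
#' stops when the counter exceeds `reject_limit`.
#'
#' @param seed a single-row `derep_set` (or any list with `seq`).
#' @param db a `derep_set`; must not contain the seed.
#' @param params a [cluster_params()] object.
#' @return the accepted rows of `db`, in scan order.
#' @export
search <- function(seed, db, params = cluster_params()) {
  if (!nrow(db)) return(db)
  idx <- search_cpp(seed$seq[[1L]], db$seq, db$abundance,
                    params$identity_threshold, params$reject_limit,
                    params$k, params$band)
  db[idx, , drop = FALSE]
}

#' De novo greedy OTU clustering
#'
#' Iteratively seeds clusters with the most abundant unassigned
#' dereplicated sequence, accepts all remaining sequences found by
#' [search()], removes them from the pool, and repeats until the pool is
#' empty. OTU ids are assigned in creation order (`OTU_1`, ...). With
#' `chimera_filter`, chimera-flagged dereps are excluded beforehand.
#'
#' @param dereps a `derep_set` (re-sorted defensively).
#' @param params a [cluster_params()] object.
#' @return an `otu_clusters` object: list with `otus` (data frame:
#'   `otu_id`, `centroid_rep_id`, `seq`, `n_dereps`, `n_reads`),
#'   `members` (per-OTU integer rows into `dereps`, centroid first, accept
#'   order), `dereps` (the clustered `derep_set`) and `params`.
#' @export
cluster_denovo <- function(dereps, params = cluster_params()) {
  if (params$chimera_filter && nrow(dereps)) {
    dereps <- dereps[!dereps$chimeric, , drop = FALSE]
  }
  if (!nrow(dereps)) {
    return(structure(list(otus = data.frame(otu_id = character(),
                                            centroid_rep_id = character(),
                                            seq = character(),
                                            n_dereps = integer(),
                                            n_reads = integer()),
                          members = list(), dereps = dereps,
                          params = params),
                     class = "otu_clusters"))
  }
  dereps <- dereps[order_dereps(dereps), , drop = FALSE]
  res <- cluster_greedy_cpp(dereps$seq, dereps$abundance,
                            s_thr = params$identity_threshold,
                            m = params$reject_limit, k = params$k,
                            band = params$band)
  otu_id <- paste0("OTU_", seq_along(res$centroids))
  otus <- data.frame(
    otu_id = otu_id,
    centroid_rep_id = dereps$rep_id[res$centroids],
    seq = dereps$seq[res$centroids],
    n_dereps = lengths(res$members),
    n_reads = vapply(res$members,
                     function(g) sum(dereps$abundance[g]), integer(1L)),
    stringsAsFactors = FALSE)
  structure(list(otus = otus, members = res$members, dereps = dereps,
                 params = params),
            class = "otu_clusters")
}

#' Read-level cluster membership
#'
#' @param clusters an [cluster_denovo()] result.
#' @return data frame with columns `read_id`, `sample`, `otu_id`.
#' @export
cluster_membership <- function(clusters) {
  if (!nrow(clusters$otus)) {
    return(data.frame(read_id = character(), sample = character(),
                      otu_id = character(), stringsAsFactors = FALSE))
  }
  per_otu <- lapply(seq_along(clusters$members), function(c) {
    g <- clusters$members[[c]]
    data.frame(read_id = unlist(clusters$dereps$member_ids[g],
                                use.names = FALSE),
               sample = unlist(clusters$dereps$member_samples[g],
                               use.names = FALSE),
               otu_id = clusters$otus$otu_id[c],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_otu)
}

#' @export
print.otu_clusters <- function(x, ...) {
  cat("otu_clusters:", nrow(x$otus), "OTUs,",
      sum(x$otus$n_reads), "reads,",
      "threshold", x$params$identity_threshold, "\n")
  invisible(x)
}

#' Reference-based read assignment
#'
#' Each read is assigned to the reference with the highest gap-ignoring
#' identity among those at or above the threshold (best hit, candidates
#' ranked by k-mer similarity and scanned with the reject counter); reads
#' below threshold everywhere are `"UNASSIGNED"`.
#'
#' @param recs a record data frame.
#' @param refs a record data frame of reference sequences (non-empty).
#' @param params a [cluster_params()] object.
#' @return named character vector `read_id -> ref_id` (or
#'   `"UNASSIGNED"`).
#' @export
assign_reference <- function(recs, refs, params = cluster_params()) {
  stopifnot(nrow(refs) > 0)
  ref_ab <- rep(1L, nrow(refs))
  out <- character(nrow(recs))
  # assign per unique read sequence
  uniq <- !duplicated(recs$seq)
  hit <- vapply(recs$seq[uniq], function(q) {
    res <- assign_best_cpp(q, refs$seq, ref_ab, params$identity_threshold,
                           params$reject_limit, params$k, params$band)
    if (res[1L] > 0) refs$read_id[res[1L]] else "UNASSIGNED"
  }, character(1L))
  out <- unname(hit[recs$seq])
  names(out) <- recs$read_id
  out
}
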