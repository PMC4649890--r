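#' Map output OTUs to ground-truth source OTUs
#'
#' Each output OTU is mapped through its centroid: the source OTU of the
#' centroid representative's first member read, or `"CHIMERIC"` when that
#' read is a labelled chimera.
#'
#' @param clusters an [cluster_denovo()] result.
#' @param truth a simulator truth table (see [generate_sample()]).
#' @return named character vector `otu_id -> source_otu` (or
#'   `"CHIMERIC"`).
#' @export
map_otus <- function(clusters, truth) {
  if (!nrow(clusters$otus)) return(setNames(character(), character()))
  first_read <- vapply(seq_along(clusters$members), function(c) {
    d <- clusters$members[[c]][1L]
    clusters$dereps$member_ids[[d]][1L]
  }, character(1L))
  hit <- match(first_read, truth$read_id)
  if (anyNA(hit)) {
    stop("centroid read id(s) missing from truth: ",
         paste(first_read[is.na(hit)][1:min(3, sum(is.na(hit)))],
               collapse = ", "))
  }
  src <- ifelse(truth$kind[hit] == "normal", truth$source_otu[hit],
                "CHIMERIC")
  setNames(src, clusters$otus$otu_id)
}

#' Count redundant OTUs
#'
#' A source OTU represented by `k > 1` output OTUs contributes `k - 1`
#' redundant OTUs (artifactual splits of one true taxon); chimeric
#' mappings are excluded.
#'
#' @param map a [map_otus()] result.
#' @return integer count.
#' @export
count_redundant <- function(map) {
  src <- map[map != "CHIMERIC"]
  if (!length(src)) return(0L)
  sum(pmax(0L, table(src) - 1L))
}

#' Count chimera-seeded output OTUs
#' @param map a [map_otus()] result.
#' @return integer count of OTUs mapped to `"CHIMERIC"`.
#' @export
count_chimeric_otus <- function(map) sum(map == "CHIMERIC")

#' Fraction of clustered reads that are labelled chimeras
#'
#' @param clusters an [cluster_denovo()] result.
#' @param truth a simulator truth table.
#' @return labelled-chimeric reads surviving in any cluster divided by
#'   the total number of clustered reads.
#' @export
chimeric_read_fraction <- function(clusters, truth) {
  mem <- cluster_membership(clusters)
  if (!nrow(mem)) return(0)
  hit <- match(mem$read_id, truth$read_id)
  mean(truth$kind[hit] != "normal", na.rm = TRUE)
}

#' Residual sum of squares of the top-20 abundance profile
#'
#' True relative abundances are the realised per-source read fractions
#' (over reads carrying a source label); estimated abundances are reads
#' in clusters mapping to each source divided by all clustered reads.
#' The RSS runs over the 20 sources with the highest true read counts; a
#' top-20 source with no mapped OTU contributes its full squared
#' abundance.
#'
#' @param clusters an [cluster_denovo()] result.
#' @param truth a simulator truth table.
#' @param map a [map_otus()] result (recomputed when `NULL`).
#' @return the residual sum of squares.
#' @export
top20_rss <- function(clusters, truth, map = NULL) {
  if (is.null(map)) map <- map_otus(clusters, truth)
  true_counts <- table(truth$source_otu[truth$kind == "normal"])
  if (length(true_counts) < 20L) {
    warning("fewer than 20 source OTUs; RSS computed over all ",
            length(true_counts))
  }
  top <- head(names(sort(true_counts, decreasing = TRUE)), 20L)
  true_rel <- as.numeric(true_counts[top]) / sum(true_counts)
  mem <- cluster_membership(clusters)
  total <- nrow(mem)
  est_rel <- vapply(top, function(s) {
    otus <- names(map)[map == s]
    if (!length(otus) || !total) return(0)
    sum(mem$otu_id %in% otus) / total
  }, numeric(1L))
  sum((est_rel - true_rel)^2)
}

#' OTU recovery ratio
#' @param n_estimated_otus,n_true_otus estimated and true OTU counts
#'   (`n_true_otus > 0`).
#' @return `n_estimated_otus / n_true_otus`.
#' @export
recovery_ratio <- function(n_estimated_otus, n_true_otus) {
  stopifnot(n_true_otus > 0)
  n_estimated_otus / n_true_otus
}
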