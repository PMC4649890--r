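#' Run the full de novo pipeline on one sample
#'
#' Preprocess, dereplicate, optionally flag and drop chimeras, and
#' cluster.
#'
#' @param recs a record data frame (one sample or several).
#' @param preproc a [preproc_params()] object, or `NULL` to skip
#'   preprocessing.
#' @param params a [cluster_params()] object.
#' @param chimera_args extra arguments for [detect_chimeras()].
#' @return list with `clusters` (an `otu_clusters`), `dereps`,
#'   `chimera_calls` (or `NULL`), `preproc_stats`.
#' @export
run_denovo <- function(recs, preproc = preproc_params(),
                       params = cluster_params(), chimera_args = list()) {
  stats <- NULL
  if (!is.null(preproc)) {
    pp <- preprocess(recs, preproc)
    recs <- pp$kept
    stats <- pp$stats
  }
  dereps <- dereplicate(recs, params$derep_mode, params)
  calls <- NULL
  if (params$chimera_filter && nrow(dereps)) {
    calls <- do.call(detect_chimeras, c(list(dereps), chimera_args))
    dereps <- flag_chimeras(dereps, calls)
  }
  clusters <- cluster_denovo(dereps, params)
  list(clusters = clusters, dereps = dereps, chimera_calls = calls,
       preproc_stats = stats)
}
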