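#' Build a samples x OTUs count table
#'
#' @param clusters an [cluster_denovo()] result (member reads must carry
#'   sample labels).
#' @return an `otu_count_table`: list with `counts` (integer matrix,
#'   samples in rows, OTUs in columns) and `centroid_map` (named
#'   character, `otu_id -> centroid rep_id`). OTUs with zero total count
#'   are excluded.
#' @export
build_otu_table <- function(clusters) {
  mem <- cluster_membership(clusters)
  if (!nrow(mem)) {
    return(new_otu_table(matrix(0L, 0L, 0L), character()))
  }
  counts <- table(factor(mem$sample), factor(mem$otu_id,
                                             levels = clusters$otus$otu_id))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]
  cmap <- setNames(clusters$otus$centroid_rep_id, clusters$otus$otu_id)
  new_otu_table(counts, cmap[colnames(counts)])
}

new_otu_table <- function(counts, centroid_map = NULL) {
  stopifnot(all(counts >= 0))
  structure(list(counts = counts, centroid_map = centroid_map),
            class = "otu_count_table")
}

#' @export
print.otu_count_table <- function(x, ...) {
  cat("otu_count_table:", nrow(x$counts), "samples x", ncol(x$counts),
      "OTUs,", sum(x$counts), "reads\n")
  invisible(x)
}

#' Rarefy an OTU table to a fixed depth
#'
#' Draws exactly `depth` reads per sample without replacement
#' (multivariate hypergeometric); samples with fewer than `depth` reads
#' are dropped with a warning.
#'
#' @param table an `otu_count_table`.
#' @param depth reads to draw per sample (positive).
#' @param seed RNG seed for reproducibility.
#' @return a rarefied `otu_count_table` (zero-total OTU columns kept so
#'   replicates stay comparable).
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (depth <= 0) stop("depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- table$counts
  tot <- rowSums(counts)
  drop <- tot < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) with fewer than ", depth,
            " reads")
    counts <- counts[!drop, , drop = FALSE]
  }
  out <- counts
  for (s in seq_len(nrow(counts))) {
    if (sum(counts[s, ]) == depth) next
    pool <- rep.int(seq_len(ncol(counts)), counts[s, ])
    pick <- sample(pool, depth, replace = FALSE)
    out[s, ] <- tabulate(pick, nbins = ncol(counts))
  }
  new_otu_table(out, table$centroid_map)
}

#' Alpha-diversity indices
#'
#' With `p_i = c_i / sum(c)`: Shannon `-sum p_i ln p_i` (natural log),
#' Simpson (Gini-Simpson) `1 - sum p_i^2`, inverse Simpson
#' `1 / sum p_i^2`.
#'
#' @param counts non-negative count vector for one sample (sum > 0).
#' @param index one of `"shannon"`, `"simpson"`, `"invsimpson"`.
#' @return the index value.
#' @export
diversity_index <- function(counts,
                            index = c("shannon", "simpson", "invsimpson")) {
  index <- match.arg(index)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero count vector")
  p <- counts / sum(counts)
  p <- p[p > 0]
  switch(index,
         shannon = -sum(p * log(p)),
         simpson = 1 - sum(p^2),
         invsimpson = 1 / sum(p^2))
}

#' Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` with singleton count `F1` and doubleton count
#' `F2`; when `F2 = 0` the bias-corrected form
#' `S_obs + F1 (F1 - 1) / 2` is used.
#'
#' @param counts non-negative count vector for one sample (sum > 0).
#' @return the estimated richness.
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero count vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Rarefaction curve
#'
#' Mean observed OTU richness per sample over random subsamples at each
#' depth.
#'
#' @param table an `otu_count_table`.
#' @param depths positive ascending depths.
#' @param replicates subsampling replicates per depth (default 10).
#' @param seed RNG seed.
#' @return data frame: `sample`, `depth`, `mean_otus`.
#' @export
rarefaction_curve <- function(table, depths, replicates = 10L,
                              seed = NULL) {
  stopifnot(all(depths > 0), !is.unsorted(depths))
  if (!is.null(seed)) set.seed(seed)
  res <- expand.grid(sample = rownames(table$counts), depth = depths,
                     stringsAsFactors = FALSE)
  res$mean_otus <- NA_real_
  for (i in seq_len(nrow(res))) {
    cnt <- table$counts[res$sample[i], ]
    if (sum(cnt) < res$depth[i]) next
    obs <- replicate(replicates, {
      pool <- rep.int(seq_along(cnt), cnt)
      sum(tabulate(sample(pool, res$depth[i]), nbins = length(cnt)) > 0)
    })
    res$mean_otus[i] <- mean(obs)
  }
  res
}
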