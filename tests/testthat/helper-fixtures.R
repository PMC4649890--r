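# fixture builders and independent oracles shared across test files

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# substitute a fraction `d` of positions to a different base
mutate_seq <- function(s, d) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(v)) < d)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1L)
  paste(v, collapse = "")
}

# substitute exactly `k` distinct positions
mutate_k <- function(s, k) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- sample(length(v), k)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1L)
  paste(v, collapse = "")
}

# a derep_set built directly from sequences + abundances
make_dereps <- function(seqs, abund, ids = sprintf("D%03d_1",
                                                   seq_along(seqs))) {
  otukit:::new_derep_set(
    rep_id = ids, seq = seqs, abundance = abund,
    member_ids = lapply(seq_along(seqs), function(i) {
      c(ids[i], sprintf("%s_m%d", sub("_1$", "", ids[i]),
                        seq_len(abund[i] - 1L))[abund[i] > 1L])
    }),
    member_samples = lapply(abund, function(a) rep("S1", a)))
}

# random clustering instance: a few sequence families with sub-threshold
# and above-threshold variants plus random abundances, in canonical order
make_instance <- function(n_max = 50L, len_range = c(50L, 150L)) {
  n_fam <- sample(2:5, 1L)
  seqs <- unlist(lapply(seq_len(n_fam), function(f) {
    base <- random_dna(sample(len_range[1L]:len_range[2L], 1L))
    c(base, replicate(sample(1:8, 1L), mutate_seq(base, runif(1, 0, 0.08))))
  }))
  seqs <- unique(seqs)
  if (length(seqs) > n_max) seqs <- seqs[seq_len(n_max)]
  abund <- sample(1:25, length(seqs), replace = TRUE)
  o <- order(-abund, -nchar(seqs), seqs, method = "radix")
  make_dereps(seqs[o], abund[o])
}

# Brute-force greedy clustering oracle: for each abundance-ordered seed,
# scan ALL remaining sequences with full DP identity and accept everything
# at or above the threshold (no k-mer ordering, no early stop). Returns
# the partition as a list of sorted rep_id vectors.
greedy_bruteforce <- function(dereps, thr) {
  active <- seq_len(nrow(dereps))
  out <- list()
  while (length(active)) {
    seed <- active[1L]
    rest <- active[-1L]
    acc <- rest[vapply(rest, function(t) {
      pairwise_identity(global_align(dereps$seq[seed],
                                     dereps$seq[t])) >= thr
    }, logical(1L))]
    out[[length(out) + 1L]] <- sort(dereps$rep_id[c(seed, acc)])
    active <- setdiff(active, c(seed, acc))
  }
  out[order(vapply(out, `[`, character(1L), 1L))]
}

partition_of <- function(clusters) {
  out <- lapply(seq_along(clusters$members), function(c) {
    sort(clusters$dereps$rep_id[clusters$members[[c]]])
  })
  out[order(vapply(out, `[`, character(1L), 1L))]
}

# error-free, full-quality model for constructing clean reads
clean_model <- function() {
  error_model(sub_rate_start = 0, sub_rate_end = 0,
              homopolymer_indel_coeff = 0, qual_mean_start = 40,
              qual_mean_end = 40, qual_sd = 0)
}
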