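#' Generate a synthetic marker-gene reference pool
#'
#' Builds `n` 16S-like reference amplicons by substituting bases of a
#' common random ancestor at per-sequence rates drawn uniformly from
#' `divergence`, so any two references differ at roughly the sum of their
#' rates. Substitution-only mutation keeps all references the same
#' length, which makes position-wise chimera construction exact.
#'
#' @param n number of references (default 500).
#' @param len amplicon length in bp (default 550, a V3-V5-like span).
#' @param divergence range of per-sequence substitution rates versus the
#'   ancestor (default 0.03-0.25).
#' @param seed RNG seed.
#' @return a record data frame with ids `REF_0001`, ... and `sample =
#'   "ref"`.
#' @export
make_reference_pool <- function(n = 500L, len = 550L,
                                divergence = c(0.03, 0.25), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, len, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    d <- runif(1L, divergence[1L], divergence[2L])
    s <- anc
    hit <- which(runif(len) < d)
    if (length(hit)) {
      s[hit] <- vapply(s[hit],
                       function(b) sample(setdiff(bases, b), 1L),
                       character(1L))
    }
    paste(s, collapse = "")
  }, character(1L))
  seq_records(sprintf("REF_%04d", seq_len(n)), seqs, sample = "ref")
}

#' Draw a power-law rank-abundance community
#'
#' Relative abundance of rank `i` is proportional to `i^-alpha`;
#' reference sequences are drawn from the pool without replacement.
#'
#' @param n_otus community richness.
#' @param alpha power-law exponent (0 = uniform; default 1).
#' @param refs a reference record data frame with at least `n_otus` rows.
#' @param seed RNG seed.
#' @return a `community_profile`: list with `otu_refs` (data frame
#'   `otu_id`, `seq`), `rel_abund` (sums to 1) and `alpha`.
#' @export
sample_community <- function(n_otus, alpha = 1, refs, seed = NULL) {
  if (n_otus > nrow(refs)) stop("n_otus exceeds the reference pool size")
  if (!is.null(seed)) set.seed(seed)
  pick <- sample(nrow(refs), n_otus)
  w <- seq_len(n_otus)^(-alpha)
  structure(list(otu_refs = data.frame(otu_id = refs$read_id[pick],
                                       seq = refs$seq[pick],
                                       stringsAsFactors = FALSE),
                 rel_abund = w / sum(w), alpha = alpha),
            class = "community_profile")
}

#' 454-like per-read error model
#'
#' Substitution probability ramps linearly 5' to 3'; homopolymer runs of
#' length `r >= 2` gain or lose one base with probability
#' `homopolymer_indel_coeff * (r - 1)`; qualities follow a linear Phred
#' ramp with Gaussian spread, and erroneous (substituted or inserted)
#' bases are re-drawn from a low-quality distribution.
#'
#' @param sub_rate_start,sub_rate_end substitution probabilities at the
#'   5' and 3' read ends.
#' @param homopolymer_indel_coeff indel probability per unit of
#'   homopolymer run length above one.
#' @param qual_mean_start,qual_mean_end,qual_sd Phred quality ramp.
#' @param err_qual_mean,err_qual_sd quality distribution of erroneous
#'   bases.
#' @return an `error_model` list.
#' @export
error_model <- function(sub_rate_start = 0.002, sub_rate_end = 0.01,
                        homopolymer_indel_coeff = 0.01,
                        qual_mean_start = 35, qual_mean_end = 20,
                        qual_sd = 4, err_qual_mean = 10, err_qual_sd = 3) {
  stopifnot(sub_rate_start >= 0, sub_rate_start <= 1, sub_rate_end >= 0,
            sub_rate_end <= 1, homopolymer_indel_coeff >= 0,
            homopolymer_indel_coeff <= 1)
  structure(as.list(environment()), class = "error_model")
}

# apply homopolymer +-1 indels; returns list(chars, inserted_positions)
apply_homopolymer_indels <- function(chars, coeff) {
  if (coeff <= 0 || !length(chars)) {
    return(list(chars = chars, inserted = integer()))
  }
  r <- rle(chars)
  ins_run <- logical(length(r$lengths))
  for (j in which(r$lengths >= 2L)) {
    if (runif(1L) < coeff * (r$lengths[j] - 1L)) {
      if (runif(1L) < 0.5) {
        r$lengths[j] <- r$lengths[j] + 1L
        ins_run[j] <- TRUE
      } else {
        r$lengths[j] <- r$lengths[j] - 1L
      }
    }
  }
  ends <- cumsum(r$lengths)
  list(chars = rep.int(r$values, r$lengths), inserted = ends[ins_run])
}

mutate_read <- function(seq, model) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hp <- apply_homopolymer_indels(chars, model$homopolymer_indel_coeff)
  chars <- hp$chars
  L <- length(chars)
  if (!L) return(list(seq = "", qual = ""))
  ramp <- if (L > 1L) (seq_len(L) - 1L) / (L - 1L) else 0
  rate <- model$sub_rate_start +
    (model$sub_rate_end - model$sub_rate_start) * ramp
  sub <- which(runif(L) < rate)
  if (length(sub)) {
    chars[sub] <- vapply(chars[sub],
                         function(b) sample(setdiff(bases, b), 1L),
                         character(1L))
  }
  qmean <- model$qual_mean_start +
    (model$qual_mean_end - model$qual_mean_start) * ramp
  qual <- round(rnorm(L, qmean, model$qual_sd))
  err <- union(sub, hp$inserted)
  if (length(err)) {
    qual[err] <- round(rnorm(length(err), model$err_qual_mean,
                             model$err_qual_sd))
  }
  qual <- pmin(pmax(qual, 2L), 40L)
  list(seq = paste(chars, collapse = ""),
       qual = rawToChar(as.raw(qual + 33L)))
}

#' Simulate one amplicon sample with ground truth
#'
#' Exactly `round(chimera_frac * n_reads)` reads are chimeric, of which
#' `round(bimera_frac * .)` are bimeras and the rest trimeras. Normal
#' reads draw their source OTU multinomially from the community profile;
#' chimera parents are distinct OTUs drawn from the same community, with
#' uniformly placed breakpoints in template coordinates. Each read is a
#' 5'-anchored prefix of its (possibly chimeric) amplicon template with
#' length drawn uniformly from `read_len`, then passed through the error
#' model.
#'
#' @param profile a [sample_community()] result.
#' @param n_reads reads to generate.
#' @param chimera_frac fraction of chimeric reads (default 0.20).
#' @param bimera_frac fraction of chimeras that are bimeras
#'   (default 0.90; the rest are trimeras).
#' @param model an [error_model()].
#' @param read_len read length range in bp (default 250-450).
#' @param sample_id sample label; read ids are `<sample_id>_<serial>`.
#' @param seed RNG seed.
#' @return list with `records` (FASTQ-ready record data frame) and
#'   `truth` (data frame `read_id`, `sample`, `kind`, `source_otu`,
#'   `parents`, `breakpoints`).
#' @export
generate_sample <- function(profile, n_reads, chimera_frac = 0.20,
                            bimera_frac = 0.90, model = error_model(),
                            read_len = c(250L, 450L), sample_id = "S1",
                            seed = NULL) {
  stopifnot(chimera_frac >= 0, chimera_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  n_chim <- round(chimera_frac * n_reads)
  n_bim <- round(bimera_frac * n_chim)
  n_tri <- n_chim - n_bim
  kind <- sample(c(rep("normal", n_reads - n_chim), rep("bimera", n_bim),
                   rep("trimera", n_tri)))
  otu_ids <- profile$otu_refs$otu_id
  tlen <- nchar(profile$otu_refs$seq[1L])
  seqs <- quals <- character(n_reads)
  source_otu <- parents <- breakpoints <- rep(NA_character_, n_reads)
  for (i in seq_len(n_reads)) {
    if (kind[i] == "normal") {
      src <- sample(length(otu_ids), 1L, prob = profile$rel_abund)
      template <- profile$otu_refs$seq[src]
      source_otu[i] <- otu_ids[src]
    } else {
      np <- if (kind[i] == "bimera") 2L else 3L
      par <- sample(length(otu_ids), np, prob = profile$rel_abund)
      bp <- sort(sample(tlen - 1L, np - 1L))
      pieces <- character(np)
      cuts <- c(0L, bp, tlen)
      for (p in seq_len(np)) {
        pieces[p] <- substr(profile$otu_refs$seq[par[p]], cuts[p] + 1L,
                            cuts[p + 1L])
      }
      template <- paste(pieces, collapse = "")
      parents[i] <- paste(otu_ids[par], collapse = ",")
      breakpoints[i] <- paste(bp, collapse = ",")
    }
    want <- round(runif(1L, read_len[1L], read_len[2L]))
    prefix <- substr(template, 1L, min(nchar(template), want))
    mut <- mutate_read(prefix, model)
    seqs[i] <- mut$seq
    quals[i] <- mut$qual
  }
  ids <- sprintf("%s_%06d", sample_id, seq_len(n_reads))
  list(records = seq_records(ids, seqs, quals, sample = sample_id),
       truth = data.frame(read_id = ids, sample = sample_id, kind = kind,
                          source_otu = source_otu, parents = parents,
                          breakpoints = breakpoints,
                          stringsAsFactors = FALSE))
}

#' Simulate a 10-sample benchmark-style dataset
#'
#' Convenience preset: one 200-OTU power-law community, ten independent
#' 5000-read samples with 20% chimeras (90% bimeras / 10% trimeras),
#' shared community structure across samples.
#'
#' @param refs a reference pool with at least `n_otus` sequences.
#' @param seed base RNG seed; sample `i` uses `seed + i`.
#' @param n_samples,n_reads,n_otus,alpha,chimera_frac,bimera_frac,model
#'   preset knobs (defaults as above).
#' @param out_dir optional directory: writes `S01.fastq`, ... and
#'   `truth.tsv`.
#' @return list with `profile`, `samples` (per-sample record data
#'   frames) and `truth` (row-bound truth table).
#' @export
make_16s10_like <- function(refs, seed = 0L, n_samples = 10L,
                            n_reads = 5000L, n_otus = 200L, alpha = 1,
                            chimera_frac = 0.20, bimera_frac = 0.90,
                            model = error_model(), out_dir = NULL) {
  profile <- sample_community(n_otus, alpha, refs, seed = seed)
  samples <- vector("list", n_samples)
  names(samples) <- sprintf("S%02d", seq_len(n_samples))
  truth <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sim <- generate_sample(profile, n_reads, chimera_frac, bimera_frac,
                           model, sample_id = names(samples)[i],
                           seed = seed + i)
    samples[[i]] <- sim$records
    truth[[i]] <- sim$truth
  }
  truth <- do.call(rbind, truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(samples)) {
      write_seqs(samples[[i]],
                 file.path(out_dir, paste0(names(samples)[i], ".fastq")))
    }
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(profile = profile, samples = samples, truth = truth)
}
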