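#' Preprocessing parameters
#'
#' @param primer5,primer3 optional IUPAC primer strings searched at the 5'
#'   and 3' read ends by semi-global alignment.
#' @param max_primer_error_rate maximum allowed edit errors as a fraction
#'   of the primer length (default 0.1).
#' @param qual_threshold Phred threshold for the sliding-window quality
#'   truncation (default 20).
#' @param window_frac window length as a fraction of the read length;
#'   fixed at 0.10.
#' @param min_len minimum read length kept after trimming (default 200).
#' @param require_primer5 discard reads whose 5' primer is not found;
#'   defaults to `TRUE` whenever `primer5` is given.
#' @return a `preproc_params` list.
#' @export
preproc_params <- function(primer5 = NULL, primer3 = NULL,
                           max_primer_error_rate = 0.1,
                           qual_threshold = 20, window_frac = 0.10,
                           min_len = 200,
                           require_primer5 = !is.null(primer5)) {
  stopifnot(max_primer_error_rate >= 0, max_primer_error_rate <= 1,
            qual_threshold >= 0, min_len >= 1, window_frac > 0)
  for (p in c(primer5, primer3)) {
    if (grepl(sprintf("[^%sU]", IUPAC_CHARS), toupper(p)))
      stop("primer is not valid IUPAC DNA: ", p)
  }
  structure(list(primer5 = if (is.null(primer5)) NULL else toupper(primer5),
                 primer3 = if (is.null(primer3)) NULL else toupper(primer3),
                 max_primer_error_rate = max_primer_error_rate,
                 qual_threshold = qual_threshold, window_frac = window_frac,
                 min_len = min_len, require_primer5 = require_primer5),
            class = "preproc_params")
}

subset_read <- function(recs, i, from, to) {
  # trim record i of `recs` to seq[from..to], qualities in lockstep
  if (to < from) {
    recs$seq[i] <- ""
    if (!is.na(recs$qual[i])) recs$qual[i] <- ""
  } else {
    recs$seq[i] <- substr(recs$seq[i], from, to)
    if (!is.na(recs$qual[i])) recs$qual[i] <- substr(recs$qual[i], from, to)
  }
  recs
}

#' Trim PCR primers by semi-global alignment
#'
#' The 5' primer is located anywhere in the read (free read end-gaps, unit
#' edit costs, IUPAC-aware zero-cost matches); if found within the error
#' budget, everything from the read start through the primer match end is
#' removed. The 3' primer is handled symmetrically, removing from the
#' match start to the read end. With `require_primer5`, reads lacking a 5'
#' match are discarded.
#'
#' @param recs a record data frame.
#' @param params a [preproc_params()] object.
#' @return list with elements `kept` (trimmed records) and `discarded`
#'   (number of reads dropped for a missing 5' primer).
#' @export
trim_primer <- function(recs, params) {
  discarded <- 0L
  if (!nrow(recs)) return(list(kept = recs, discarded = 0L))
  drop <- logical(nrow(recs))
  if (!is.null(params$primer5)) {
    budget <- params$max_primer_error_rate * nchar(params$primer5)
    for (i in seq_len(nrow(recs))) {
      loc <- primer_locate_cpp(recs$seq[i], params$primer5, TRUE)
      if (loc[1L] <= budget) {
        recs <- subset_read(recs, i, loc[2L] + 1L, nchar(recs$seq[i]))
      } else if (params$require_primer5) {
        drop[i] <- TRUE
      }
    }
  }
  if (!is.null(params$primer3)) {
    budget <- params$max_primer_error_rate * nchar(params$primer3)
    for (i in seq_len(nrow(recs))) {
      if (drop[i] || !nchar(recs$seq[i])) next
      loc <- primer_locate_cpp(recs$seq[i], params$primer3, FALSE)
      if (loc[1L] <= budget) {
        recs <- subset_read(recs, i, 1L, nchar(recs$seq[i]) - loc[2L])
      }
    }
  }
  list(kept = recs[!drop, , drop = FALSE], discarded = sum(drop))
}

#' Sliding-window quality truncation
#'
#' Windows of length `max(1, round(window_frac * L))` slide 5' to 3' in
#' steps of one base; at the first window whose mean Phred quality drops
#' below `qual_threshold` the read is truncated at the first
#' below-threshold base inside that window. Reads with no failing window
#' are unchanged.
#'
#' @inheritParams trim_primer
#' @return the records with sequences and qualities truncated.
#' @export
quality_trim <- function(recs, params) {
  if (!nrow(recs)) return(recs)
  if (any(is.na(recs$qual))) stop("quality_trim requires qualities")
  keep <- qtrim_len_cpp(recs$qual, params$qual_threshold, params$window_frac)
  recs$seq <- substr(recs$seq, 1L, keep)
  recs$qual <- substr(recs$qual, 1L, keep)
  recs
}

#' Strip terminal and contiguous Ns
#'
#' Trailing Ns are removed from the 3' end; the read is then truncated
#' immediately before the first run of two or more consecutive Ns. Single
#' isolated internal Ns are retained (they count as mismatches downstream).
#'
#' @param recs a record data frame.
#' @return the records with N-trimmed sequences.
#' @export
strip_ns <- function(recs) {
  if (!nrow(recs)) return(recs)
  keep <- nchar(sub("N+$", "", recs$seq))
  run <- regexpr("NN", substr(recs$seq, 1L, keep), fixed = TRUE)
  keep <- ifelse(run > 0L, run - 1L, keep)
  recs$seq <- substr(recs$seq, 1L, keep)
  recs$qual <- ifelse(is.na(recs$qual), recs$qual,
                      substr(recs$qual, 1L, keep))
  recs
}

#' Run the full preprocessing pipeline
#'
#' Stage order: primer trimming, sliding-window quality truncation,
#' N-stripping, minimum-length filter.
#'
#' @inheritParams trim_primer
#' @return list with `kept` (surviving records) and `stats` (a data frame
#'   with per-stage discarded/kept counts plus the overall pass fraction
#'   as an attribute).
#' @export
preprocess <- function(recs, params = preproc_params()) {
  n_in <- nrow(recs)
  if (!n_in) {
    warning("empty input to preprocess()")
    stats <- data.frame(stage = c("input", "primer", "length"),
                        discarded = c(0L, 0L, 0L), kept = c(0L, 0L, 0L))
    attr(stats, "pass_fraction") <- 0
    return(list(kept = recs, stats = stats))
  }
  pr <- trim_primer(recs, params)
  recs <- pr$kept
  if (!all(is.na(recs$qual))) recs <- quality_trim(recs, params)
  recs <- strip_ns(recs)
  short <- nchar(recs$seq) < params$min_len
  kept <- recs[!short, , drop = FALSE]
  stats <- data.frame(
    stage = c("input", "primer", "length"),
    discarded = c(0L, pr$discarded, sum(short)),
    kept = c(n_in, n_in - pr$discarded, nrow(kept)))
  attr(stats, "pass_fraction") <- nrow(kept) / n_in
  list(kept = kept, stats = stats)
}
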