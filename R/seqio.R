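IUPAC_CHARS <- "ACGTNRYSWKMBDHV"

#' Construct a table of sequence records
#'
#' The basic container used throughout the package is a plain data frame
#' with one row per read and columns `read_id`, `sample`, `seq`
#' (uppercase DNA) and `qual` (Phred+33 quality string, or `NA` for
#' FASTA-derived records).
#'
#' @param read_id character vector of unique read identifiers.
#' @param seq character vector of DNA sequences (uppercased on input).
#' @param qual optional character vector of Phred+33 quality strings, the
#'   same lengths as `seq`.
#' @param sample sample labels; by default derived from `read_id` via
#'   [parse_sample()].
#' @return a `data.frame` with columns `read_id`, `sample`, `seq`, `qual`.
#' @export
seq_records <- function(read_id, seq, qual = NA_character_, sample = NULL) {
  seq <- toupper(seq)
  stopifnot(length(read_id) == length(seq))
  bad <- grepl(sprintf("[^%s]", IUPAC_CHARS), seq)
  if (any(bad)) {
    stop("invalid sequence characters in record(s) ",
         paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  if (length(qual) == 1L) qual <- rep(qual, length(seq))
  has_q <- !is.na(qual)
  if (any(nchar(qual[has_q]) != nchar(seq[has_q]))) {
    stop("quality string length differs from sequence length in record(s) ",
         paste(which(has_q & nchar(qual) != nchar(seq))[1:1], collapse = ", "))
  }
  if (is.null(sample)) sample <- parse_sample(read_id)
  data.frame(read_id = as.character(read_id), sample = as.character(sample),
             seq = seq, qual = as.character(qual),
             stringsAsFactors = FALSE)
}

#' Read sequence records from FASTA or FASTQ
#'
#' FASTA parsing (any line wrapping) is delegated to
#' [Biostrings::readDNAStringSet()]; FASTQ (strictly 4 lines per record,
#' Phred+33) is parsed in-package so that malformed records are reported
#' by index. Lowercase bases are uppercased; FASTA records get `qual = NA`.
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (from the file
#'   extension, falling back to the first byte).
#' @param sample optional single sample label for the whole file; default
#'   derives per-read labels from the read-id prefix (see
#'   [parse_sample()]).
#' @return a record data frame (see [seq_records()]), in file order.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq"),
                      sample = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "fastq"
      else if (ext %in% c("fa", "fasta", "fna", "ffn")) "fasta"
      else {
        first <- readChar(path, 1L)
        if (identical(first, "@")) "fastq" else "fasta"
      }
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop("FASTA parse error in '", path,
                                             "': ", conditionMessage(e)))
    ids <- sub("\\s.*$", "", names(set))
    recs <- seq_records(ids, as.character(set), sample = sample %||%
                          parse_sample(ids))
    return(recs)
  }
  lines <- readLines(path)
  # drop a single trailing empty line, if any
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) {
    return(seq_records(character(), character(), character(),
                       sample = character()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: record ", length(lines) %/% 4L + 1L,
         " is incomplete in '", path, "'")
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- !startsWith(hdr, "@") | !startsWith(plus, "+")
  if (any(bad)) stop("malformed FASTQ record ", which(bad)[1L], " in '",
                     path, "'")
  bad <- nchar(seq) != nchar(qual)
  if (any(bad)) {
    stop("FASTQ record ", which(bad)[1L],
         ": sequence and quality lengths differ")
  }
  if (any(nchar(seq) == 0L)) {
    stop("FASTQ record ", which(nchar(seq) == 0L)[1L], ": empty sequence")
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  seq_records(ids, seq, qual, sample = sample %||% parse_sample(ids))
}

#' Write sequence records to FASTA or FASTQ
#'
#' FASTA output is wrapped at 80 columns. FASTQ output requires qualities
#' on every record.
#'
#' @param recs a record data frame.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(recs, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(recs$seq)
    names(set) <- recs$read_id
    Biostrings::writeXStringSet(set, path, width = 80L)
  } else {
    if (any(is.na(recs$qual))) stop("FASTQ output requires qualities")
    out <- character(4L * nrow(recs))
    out[seq(1L, length(out), 4L)] <- paste0("@", recs$read_id)
    out[seq(2L, length(out), 4L)] <- recs$seq
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- recs$qual
    writeLines(out, path)
  }
  invisible(path)
}

#' Derive sample labels from read identifiers
#'
#' The default rule takes the substring before the first underscore
#' (the post-demultiplexing convention `SAMPLE_SERIAL`). A custom regular
#' expression with exactly one capture group can override it. Ids without
#' the separator fall back to the whole id, with a warning.
#'
#' @param read_id character vector of read ids.
#' @param pattern optional regex with one capture group.
#' @return character vector of sample labels.
#' @export
parse_sample <- function(read_id, pattern = NULL) {
  if (!length(read_id)) return(character())
  stopifnot(all(nzchar(read_id)))
  if (is.null(pattern)) {
    has_sep <- grepl("_", read_id, fixed = TRUE)
    if (!all(has_sep)) {
      warning("read id(s) without '_' separator; whole id used as sample: ",
              read_id[!has_sep][1L])
    }
    return(ifelse(has_sep, sub("_.*$", "", read_id), read_id))
  }
  m <- regmatches(read_id, regexec(pattern, read_id))
  bad <- lengths(m) < 2L
  if (any(bad)) {
    stop("sample pattern matched nothing for read id(s): ",
         paste(read_id[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  vapply(m, `[`, character(1L), 2L)
}

#' Phred integer qualities of one record
#' @param qual a Phred+33 quality string.
#' @return integer vector of Phred scores.
#' @export
phred_ints <- function(qual) {
  if (is.na(qual)) return(NULL)
  as.integer(charToRaw(qual)) - 33L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
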