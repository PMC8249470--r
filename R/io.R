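## Reading, writing and pre-processing of small RNA libraries.

#' Construct a small RNA library object
#'
#' A library is a set of collapsed reads: each distinct sequence appears once
#' with its total cloning/sequencing count.
#'
#' @param reads data.frame with columns `sequence` and `count`.
#' @param library_id,genotype identifying labels.
#' @param log character vector of processing-log lines
#'   (`stage<TAB>reads_in<TAB>reads_out`).
#' @return an object of class `smallrna_library`.
#' @export
smallrna_library <- function(reads, library_id = "lib1",
                             genotype = library_id, log = character(0)) {
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  if (anyDuplicated(reads$sequence))
    reads <- collapse_reads(reads$sequence, reads$count)
  if (nrow(reads) && any(reads$count < 1))
    stop("read counts must be >= 1", call. = FALSE)
  rownames(reads) <- NULL
  structure(list(library_id = library_id, genotype = genotype,
                 reads = reads[, c("sequence", "count")],
                 totals = NULL, log = log),
            class = "smallrna_library")
}

#' @export
print.smallrna_library <- function(x, ...) {
  cat("Small RNA library", sQuote(x$library_id),
      sprintf("(genotype %s): %d distinct sequences, %d reads\n",
              x$genotype, nrow(x$reads), sum(x$reads$count)))
  if (!is.null(x$totals)) {
    cat("  class totals:\n")
    print(x$totals)
  }
  invisible(x)
}

#' Load small RNA reads from FASTA or FASTQ
#'
#' Identical sequences are collapsed with counts summed.  With
#' `collapsed_header = TRUE`, FASTA/FASTQ identifiers ending in `_x<COUNT>`
#' (the collapsed-read convention, e.g. `>read4_x17`) contribute that count.
#' Reads containing N are discarded with a logged count; any other non-ACGT
#' character is a parse error.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @param collapsed_header parse `_x<COUNT>` suffixes in identifiers.
#' @param library_id,genotype labels for the library.
#' @return a `smallrna_library`.
#' @export
load_reads <- function(path, format = c("fasta", "fastq"),
                       collapsed_header = FALSE,
                       library_id = sub("\\.[^.]*$", "", basename(path)),
                       genotype = library_id) {
  format <- match.arg(format)
  seqs <- Biostrings::readBStringSet(path, format = format)
  ids <- names(seqs)
  seqs <- toupper(as.character(seqs))
  if (length(seqs) == 0L)
    warning("empty input file: ", path, call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("record %d in %s contains non-ACGTN characters",
                 which(bad)[1], path), call. = FALSE)
  count <- rep(1L, length(seqs))
  if (collapsed_header && length(ids)) {
    m <- regmatches(ids, regexpr("_x([0-9]+)\\s*$", ids))
    has <- nchar(m) > 0
    count[has] <- as.integer(sub("_x", "", m[has]))
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  lg <- c(log_line("load", length(seqs), length(seqs)))
  if (any(has_n)) {
    lg <- c(lg, log_line("drop_N", length(seqs), sum(!has_n)))
    seqs <- seqs[!has_n]; count <- count[!has_n]
  }
  reads <- if (length(seqs)) collapse_reads(seqs, count) else
    data.frame(sequence = character(0), count = integer(0))
  smallrna_library(reads, library_id = library_id, genotype = genotype,
                   log = lg)
}

#' Write a library as collapsed FASTA
#'
#' Headers follow the `>read<N>_x<COUNT>` convention.
#'
#' @param lib a `smallrna_library`.
#' @param path output FASTA path.
#' @param format `"fasta"` (default) or `"fastq"` (constant quality `I`).
#' @export
write_library <- function(lib, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ids <- sprintf("read%d_x%d", seq_len(nrow(lib$reads)), lib$reads$count)
  x <- Biostrings::DNAStringSet(lib$reads$sequence)
  names(x) <- ids
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else {
    q <- Biostrings::BStringSet(strrep("I", nchar(lib$reads$sequence)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Trim a 3' adapter from every read
#'
#' The leftmost exact occurrence of an adapter prefix (length >=
#' `min_overlap`) anchored at the read's 3' end is removed.  Reads with no
#' such occurrence have an undefined insert and are discarded (unless
#' `keep_untrimmed = TRUE`, which retains them unmodified).  The result is
#' re-collapsed.
#'
#' @param lib a `smallrna_library`.
#' @param adapter adapter DNA sequence (length >= `min_overlap`).
#' @param min_overlap minimal adapter prefix length at the 3' end.
#' @param keep_untrimmed keep reads lacking the adapter instead of dropping
#'   them.
#' @return a trimmed `smallrna_library`.
#' @export
trim_adapter <- function(lib, adapter, min_overlap = 5L,
                         keep_untrimmed = FALSE) {
  stopifnot(inherits(lib, "smallrna_library"))
  if (nchar(adapter) < min_overlap)
    stop("adapter shorter than min_overlap", call. = FALSE)
  seqs <- lib$reads$sequence
  insert_len <- vapply(seqs, function(s) {
    n <- nchar(s)
    for (p in seq_len(max(0L, n - min_overlap + 1L))) {
      tail_len <- n - p + 1L
      if (substring(s, p, n) ==
          substring(adapter, 1L, min(tail_len, nchar(adapter))) &&
          tail_len <= nchar(adapter))
        return(p - 1L)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  hit <- !is.na(insert_len)
  out_seq <- character(0); out_cnt <- integer(0)
  if (any(hit)) {
    out_seq <- substring(seqs[hit], 1L, insert_len[hit])
    out_cnt <- lib$reads$count[hit]
  }
  if (keep_untrimmed && any(!hit)) {
    out_seq <- c(out_seq, seqs[!hit])
    out_cnt <- c(out_cnt, lib$reads$count[!hit])
  }
  keep <- nchar(out_seq) > 0L
  reads <- if (any(keep)) collapse_reads(out_seq[keep], out_cnt[keep]) else
    data.frame(sequence = character(0), count = integer(0))
  res <- smallrna_library(reads, lib$library_id, lib$genotype,
                          log = c(lib$log,
                                  log_line("trim_adapter",
                                           sum(lib$reads$count),
                                           sum(reads$count))))
  res
}

#' Size-select reads by length
#'
#' Retains reads with `min_len <= length <= max_len` (inclusive bounds, as
#' in a gel size selection window); counts are preserved.
#'
#' @param lib a `smallrna_library`.
#' @param min_len,max_len inclusive length bounds.
#' @return a `smallrna_library`.
#' @export
size_select <- function(lib, min_len, max_len) {
  stopifnot(inherits(lib, "smallrna_library"),
            min_len > 0, min_len <= max_len)
  len <- nchar(lib$reads$sequence)
  keep <- len >= min_len & len <= max_len
  reads <- lib$reads[keep, , drop = FALSE]
  rownames(reads) <- NULL
  smallrna_library(reads, lib$library_id, lib$genotype,
                   log = c(lib$log,
                           log_line(sprintf("size_select_%d_%d",
                                            min_len, max_len),
                                    sum(lib$reads$count),
                                    sum(reads$count))))
}
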