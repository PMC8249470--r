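## Shared internal helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA character strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' ACGTN).  Used internally wherever sequences are carried as characters
#' rather than `Biostrings` objects.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTAA"))
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## sample() without the length-1 surprise
sample_int <- function(pool, size, replace = FALSE, prob = NULL) {
  pool[sample.int(length(pool), size, replace = replace, prob = prob)]
}

stopifnot_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", nm),
         call. = FALSE)
  invisible(x)
}

check_length_dist <- function(d, nm, allowed) {
  if (length(d) == 0L) stop(sprintf("'%s' is empty", nm), call. = FALSE)
  len <- as.integer(names(d))
  if (anyNA(len) || !all(len %in% allowed))
    stop(sprintf("'%s' has lengths outside {%s}", nm,
                 paste(range(allowed), collapse = "..")), call. = FALSE)
  if (any(d < 0) || abs(sum(d) - 1) > 1e-9)
    stop(sprintf("'%s' must be non-negative and sum to 1", nm), call. = FALSE)
  invisible(d)
}

log_line <- function(stage, n_in, n_out) {
  sprintf("%s\t%d\t%d", stage, as.integer(n_in), as.integer(n_out))
}

## count-weighted aggregation of a read table by sequence
collapse_reads <- function(sequence, count) {
  agg <- rowsum(as.numeric(count), group = sequence, reorder = TRUE)
  data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
             stringsAsFactors = FALSE)
}
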