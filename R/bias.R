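## 1U / 10A nucleotide bias statistics and positional base composition.
## All statistics are cloning/sequencing-count weighted by default, matching
## the weighting of the ping-pong histogram; `weight = "unique"` treats each
## distinct sequence once.

bias_weights <- function(reads, weight = c("count", "unique")) {
  weight <- match.arg(weight)
  if (weight == "count") as.numeric(reads$count) else
    rep(1, nrow(reads))
}

#' Fraction of reads with U (T) at position 1
#'
#' @param reads data.frame with `sequence` and `count`.
#' @param weight `"count"` (default) or `"unique"`.
#' @return percent in 0..100, or `NA` for an empty subset.
#' @export
frac_first_u <- function(reads, weight = c("count", "unique")) {
  if (nrow(reads) == 0L) return(NA_real_)
  w <- bias_weights(reads, weight)
  100 * sum(w[substring(reads$sequence, 1L, 1L) == "T"]) / sum(w)
}

#' 10A bias of sense reads
#'
#' Percentage of (by default non-1U) sense reads carrying A at position 10
#' (1-based).  Sense orientation must be established upstream (TE
#' alignment); the function operates on the read subset it is given.
#'
#' @param sense_reads data.frame with `sequence` and `count` (sense reads;
#'   >= 10 nt).
#' @param exclude_first_u restrict to reads whose first base is not T
#'   (default `TRUE`).
#' @param weight `"count"` (default) or `"unique"`.
#' @return percent in 0..100, or `NA` when the subset is empty after
#'   restriction.
#' @export
ten_a_bias <- function(sense_reads, exclude_first_u = TRUE,
                       weight = c("count", "unique")) {
  r <- sense_reads
  if (nrow(r) && any(nchar(r$sequence) < 10L))
    stop("reads shorter than 10 nt in 10A bias computation", call. = FALSE)
  if (exclude_first_u && nrow(r))
    r <- r[substring(r$sequence, 1L, 1L) != "T", , drop = FALSE]
  if (nrow(r) == 0L) return(NA_real_)
  w <- bias_weights(r, weight)
  100 * sum(w[substring(r$sequence, 10L, 10L) == "A"]) / sum(w)
}

#' Count-weighted positional base composition matrix
#'
#' Base fractions per position 1..`max_pos`; positions beyond a read's
#' length do not receive contributions from that read, so every populated
#' column sums to 1.
#'
#' @param reads data.frame with `sequence` and `count`.
#' @param max_pos rightmost position (default 29).
#' @param weight `"count"` (default) or `"unique"`.
#' @return `max_pos` x 4 matrix of fractions (columns A, C, G, T); rows
#'   beyond every read's length are `NA`.
#' @export
base_matrix <- function(reads, max_pos = 29L, weight = c("count", "unique")) {
  out <- matrix(NA_real_, nrow = max_pos, ncol = 4,
                dimnames = list(seq_len(max_pos), DNA_BASES))
  if (nrow(reads) == 0L) return(out)
  w <- bias_weights(reads, weight)
  len <- nchar(reads$sequence)
  for (p in seq_len(max_pos)) {
    sel <- len >= p
    if (!any(sel)) next
    b <- substring(reads$sequence[sel], p, p)
    tot <- sum(w[sel])
    out[p, ] <- vapply(DNA_BASES, function(x) sum(w[sel][b == x]) / tot,
                       numeric(1))
  }
  out
}

#' Bias report for a set of TE-aligned reads
#'
#' Pools reads (default) or computes per family: the 1U fraction among
#' antisense reads, the 10A fraction among sense non-1U reads, and the full
#' base matrix for each strand.
#'
#' @param alignments TE alignments (data.frame from
#'   [map_library_to_panel()]).  A read aligned at several placements with
#'   the same strand within a family is counted once per (sequence, strand,
#'   family) for the bias statistics.
#' @param scope `"all"` (pool all families, default) or a family id.
#' @param weight `"count"` or `"unique"`.
#' @return list with `scope`, `frac_1U_antisense`, `frac_10A_sense_non1U`,
#'   `frac_10A_sense_all`, `n_sense`, `n_antisense` (count-weighted) and
#'   `base_matrix_sense`/`base_matrix_antisense`.
#' @export
bias_report <- function(alignments, scope = "all",
                        weight = c("count", "unique")) {
  a <- alignments
  if (scope != "all") a <- a[a$family == scope, , drop = FALSE]
  a <- a[!duplicated(paste(a$sequence, a$strand)), , drop = FALSE]
  sense <- a[a$strand == "sense", c("sequence", "count"), drop = FALSE]
  anti <- a[a$strand == "antisense", c("sequence", "count"), drop = FALSE]
  list(scope = scope,
       frac_1U_antisense = frac_first_u(anti, weight = weight),
       frac_10A_sense_non1U = ten_a_bias(sense, TRUE, weight = weight),
       frac_10A_sense_all = ten_a_bias(sense, FALSE, weight = weight),
       n_sense = sum(sense$count), n_antisense = sum(anti$count),
       base_matrix_sense = base_matrix(sense, weight = weight),
       base_matrix_antisense = base_matrix(anti, weight = weight))
}
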