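## Genomic window tiling, 5'-end window counting, the control/reduction
## filters and per-window cluster fold changes.

#' Tile a genome into fixed-size windows
#'
#' Non-overlapping half-open tiles `[k*size, (k+1)*size)` per chromosome;
#' the last tile is truncated at the chromosome end.  Windows never span
#' chromosomes.
#'
#' @param genome named character vector of chromosome sequences, a
#'   `te_panel`, or a named numeric vector of chromosome lengths.
#' @param size window size in nt (>= 100).
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive).
#' @export
#' @examples
#' make_windows(c(chr1 = 12000), size = 5000)
make_windows <- function(genome, size) {
  stopifnot(size >= 100)
  if (inherits(genome, "te_panel")) genome <- genome$genome
  lens <- if (is.numeric(genome)) genome else nchar(genome)
  size <- as.integer(size)
  out <- lapply(names(lens), function(ch) {
    L <- as.integer(lens[[ch]])
    starts <- seq(0L, L - 1L, by = size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## 5'-end genomic coordinate of an alignment: start for +, end-1 for -
five_prime_coord <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$start, alignments$end - 1L)
}

#' Count reads per window, normalized per million miRNAs
#'
#' A read placement is assigned to the single window containing its 5'-end
#' genomic coordinate (alignment start on `+`, alignment end - 1 on `-`), so
#' boundary-spanning reads are never double counted.  By default only
#' uniquely mapping reads are counted.
#'
#' @param genome_alignments result of [map_library_to_genome()].
#' @param windows result of [make_windows()] (regular tiling).
#' @param total_mirna the library's miRNA total (> 0).
#' @param unique_only count only placements of uniquely mapping reads
#'   (default `TRUE`).
#' @param size the tile size used to build `windows` (inferred when
#'   missing).
#' @return the `windows` data.frame with columns `count` and `rpm_mirna`.
#' @export
window_counts <- function(genome_alignments, windows, total_mirna,
                          unique_only = TRUE, size = NULL) {
  if (is.null(size)) size <- max(windows$end - windows$start)
  gal <- genome_alignments
  if (unique_only) gal <- gal[gal$unique, , drop = FALSE]
  windows$count <- 0
  if (nrow(gal)) {
    fp <- five_prime_coord(gal)
    key <- paste(gal$chrom, fp %/% size)
    wkey <- paste(windows$chrom, windows$start %/% size)
    mass <- rowsum(as.numeric(gal$count), key)
    idx <- match(rownames(mass), wkey)
    ok <- !is.na(idx)
    windows$count[idx[ok]] <- mass[ok, 1]
  }
  windows$rpm_mirna <- normalize_per_million_mirna(windows$count,
                                                   total_mirna)
  windows
}

#' Build a multi-library window table
#'
#' @param counts_per_library named list of [window_counts()] results (same
#'   tiling) keyed by library id.
#' @param total_mirna named vector of miRNA totals per library id.
#' @return data.frame `chrom`, `start`, `end`, then one `rpm.<id>` column
#'   per library; miRNA totals kept in attribute `total_mirna`.
#' @export
window_table <- function(counts_per_library, total_mirna) {
  base <- counts_per_library[[1]][, c("chrom", "start", "end")]
  for (id in names(counts_per_library))
    base[[paste0("rpm.", id)]] <- counts_per_library[[id]]$rpm_mirna
  attr(base, "total_mirna") <- total_mirna
  base
}

#' Filter windows by control abundance and mutant reduction
#'
#' Keeps windows with control rpm >= `min_rpm` ("at least 5 reads per
#' million of miRNAs", inclusive) and a piRNA reduction in the mutant
#' strictly greater than `min_reduction` ("more than 80% reduction").
#'
#' @param table a [window_table()] (or any data.frame with `rpm.<id>`
#'   columns).
#' @param control_id,mutant_id library ids.
#' @param min_rpm control threshold (default 5, inclusive).
#' @param min_reduction reduction threshold (default 0.8, strict).
#' @return the table rows that pass, with logical columns
#'   `passes_control_min`, `passes_reduction` and numeric `reduction` added
#'   (attribute `flags` holds the per-window flags for all windows).
#' @export
filter_windows <- function(table, control_id, mutant_id, min_rpm = 5,
                           min_reduction = 0.8) {
  ctrl <- table[[paste0("rpm.", control_id)]]
  mut <- table[[paste0("rpm.", mutant_id)]]
  if (is.null(ctrl) || is.null(mut))
    stop("control or mutant column missing from window table", call. = FALSE)
  passes_control <- ctrl >= min_rpm
  reduction <- ifelse(ctrl > 0, (ctrl - mut) / ctrl, NA_real_)
  passes_reduction <- !is.na(reduction) & reduction > min_reduction
  out <- table[passes_control & passes_reduction, , drop = FALSE]
  out$reduction <- reduction[passes_control & passes_reduction]
  attr(out, "flags") <- data.frame(passes_control_min = passes_control,
                                   passes_reduction = passes_reduction,
                                   reduction = reduction)
  rownames(out) <- NULL
  out
}

#' Per-window log2 fold change restricted to piRNA cluster intervals
#'
#' For every window overlapping a cluster annotation interval, computes
#' `log2((rpm + eps) / (rpm_ctrl + eps_ctrl))` with the 0.5-read
#' pseudocount converted to each library's miRNA scale.
#'
#' @param table_1kb a [window_table()] built on 1-kb tiles (any tiling
#'   works; the name records the intended use).
#' @param annotation annotation data.frame; rows with class
#'   `cluster_unistrand`/`cluster_dualstrand` define the cluster intervals.
#' @param control_id control library id.
#' @param pseudo_reads pseudocount in raw reads (default 0.5).
#' @return the cluster-overlapping rows with a `cluster` column and one
#'   `log2fc.<id>` column per non-control library.
#' @export
cluster_fold_change <- function(table_1kb, annotation, control_id,
                                pseudo_reads = 0.5) {
  cl <- annotation[grepl("^cluster_", annotation$class), , drop = FALSE]
  if (nrow(cl) == 0L) stop("no cluster intervals in annotation",
                           call. = FALSE)
  wgr <- GenomicRanges::GRanges(table_1kb$chrom,
                                IRanges::IRanges(table_1kb$start + 1L,
                                                 table_1kb$end))
  cgr <- annotation_granges(cl)
  ov <- GenomicRanges::findOverlaps(wgr, cgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  out <- table_1kb[qh, , drop = FALSE]
  out$cluster <- cl$name[S4Vectors::subjectHits(ov)]
  total_mirna <- attr(table_1kb, "total_mirna")
  eps <- pseudo_reads * 1e6 / total_mirna
  ids <- sub("^rpm\\.", "", grep("^rpm\\.", names(table_1kb), value = TRUE))
  ctrl <- out[[paste0("rpm.", control_id)]]
  for (id in setdiff(ids, control_id)) {
    out[[paste0("log2fc.", id)]] <-
      log2((out[[paste0("rpm.", id)]] + eps[[id]]) /
             (ctrl + eps[[control_id]]))
  }
  rownames(out) <- NULL
  out
}

#' Export windows as BED
#'
#' chrom, start, end, name, score = rpm of `value_col`, strand `.`.
#'
#' @param windows a window table or [window_counts()] result.
#' @param path output path.
#' @param value_col numeric column written to the score field.
#' @export
write_windows_bed <- function(windows, path,
                              value_col = grep("^rpm", names(windows),
                                               value = TRUE)[1]) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    name = sprintf("win%d", seq_len(nrow(windows))),
                    score = windows[[value_col]], strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
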