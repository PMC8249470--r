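## Read classification and miRNA-normalized abundance.

#' Classify reads from genome placements and annotation intervals
#'
#' Priority order (each read gets exactly one class): a read is `miRNA` if
#' any exact genomic placement overlaps a miRNA gene interval; else `rRNA`
#' if any placement overlaps an rRNA interval; else `piRNA` if its length is
#' within `pirna_len` and any placement overlaps a repeat interval; else
#' `other`.  Reads with no placement are `other`.
#'
#' @param lib a `smallrna_library`.
#' @param genome_alignments result of [map_library_to_genome()].
#' @param annotation annotation data.frame (see [generate_te_panel()]).
#' @param pirna_len inclusive length window defining piRNA-sized reads
#'   (default 23..29).
#' @param unique_only_repeat require the repeat-overlapping placement to be
#'   unique for the piRNA class (default `FALSE`: any placement counts).
#' @return a `classified_library`: list with `library_id`, `genotype`,
#'   `reads` (sequence, count, length, class) and `totals` (named counts per
#'   class).
#' @export
classify_reads <- function(lib, genome_alignments, annotation,
                           pirna_len = c(23L, 29L),
                           unique_only_repeat = FALSE) {
  reads <- lib$reads
  reads$length <- nchar(reads$sequence)
  cls <- rep("other", nrow(reads))
  if (nrow(genome_alignments)) {
    gal <- genome_alignments
    if (nrow(gal)) {
      gr <- GenomicRanges::GRanges(
        seqnames = gal$chrom,
        ranges = IRanges::IRanges(start = gal$start + 1L, end = gal$end))
      agr <- annotation_granges(annotation)
      ov <- GenomicRanges::findOverlaps(gr, agr, ignore.strand = TRUE)
      ov_class <- agr$class[S4Vectors::subjectHits(ov)]
      hit_seq <- gal$sequence[S4Vectors::queryHits(ov)]
      hit_unique <- gal$unique[S4Vectors::queryHits(ov)]
      overlaps_class <- function(class, need_unique = FALSE) {
        sel <- ov_class == class
        if (need_unique) sel <- sel & hit_unique
        reads$sequence %in% unique(hit_seq[sel])
      }
      is_mirna <- overlaps_class("miRNA")
      is_rrna <- overlaps_class("rRNA")
      is_rep <- overlaps_class("repeat", need_unique = unique_only_repeat)
      in_len <- reads$length >= pirna_len[1] & reads$length <= pirna_len[2]
      cls[is_mirna] <- "miRNA"
      cls[!is_mirna & is_rrna] <- "rRNA"
      cls[!is_mirna & !is_rrna & is_rep & in_len] <- "piRNA"
    }
  }
  reads$class <- cls
  totals <- vapply(c("miRNA", "rRNA", "piRNA", "other"), function(k)
    sum(reads$count[reads$class == k]), numeric(1))
  structure(list(library_id = lib$library_id, genotype = lib$genotype,
                 reads = reads, totals = totals,
                 priority = c("miRNA", "rRNA", "piRNA", "other")),
            class = "classified_library")
}

#' @export
print.classified_library <- function(x, ...) {
  cat("Classified library", sQuote(x$library_id), "\n  class totals:\n")
  print(x$totals)
  cat(sprintf("  piRNA:miRNA ratio: %.3f\n",
              x$totals[["piRNA"]] / x$totals[["miRNA"]]))
  invisible(x)
}

#' Normalize a count per million miRNA reads
#'
#' The cross-library normalizer: `count * 1e6 / total_mirna`.
#'
#' @param count read count (vectorised).
#' @param total_mirna total miRNA count of the library (> 0).
#' @return reads per million miRNAs.
#' @export
normalize_per_million_mirna <- function(count, total_mirna) {
  if (length(total_mirna) != 1L || is.na(total_mirna) || total_mirna <= 0)
    stop("total_mirna must be a single positive count", call. = FALSE)
  count * 1e6 / total_mirna
}

#' Normalize a count per million non-rRNA library reads
#'
#' RPM after rRNA reads are discarded: `count * 1e6 / total_nonrrna`.
#'
#' @param count read count (vectorised).
#' @param total_nonrrna total library count excluding rRNA (> 0).
#' @return reads per million.
#' @export
normalize_rpm_total <- function(count, total_nonrrna) {
  if (length(total_nonrrna) != 1L || is.na(total_nonrrna) ||
      total_nonrrna <= 0)
    stop("total_nonrrna must be a single positive count", call. = FALSE)
  count * 1e6 / total_nonrrna
}

#' Count-weighted length distribution per class
#'
#' @param classified a `classified_library`.
#' @param classes classes to tabulate (default all present).
#' @param lengths length range of the histogram (default 19..29).
#' @return matrix lengths x classes of summed counts.
#' @export
length_distribution <- function(classified,
                                classes = unique(classified$reads$class),
                                lengths = 19:29) {
  r <- classified$reads
  out <- sapply(classes, function(k) {
    sel <- r$class == k
    vapply(lengths, function(l) sum(r$count[sel & r$length == l]),
           numeric(1))
  })
  out <- matrix(out, nrow = length(lengths),
                dimnames = list(lengths, classes))
  out
}

#' Ratio of repeat-derived piRNAs to miRNAs
#'
#' @param classified a `classified_library`.
#' @return `totals["piRNA"] / totals["miRNA"]`.
#' @export
pirna_mirna_ratio <- function(classified) {
  tm <- classified$totals[["miRNA"]]
  if (is.na(tm) || tm <= 0)
    stop("miRNA total is zero; ratio undefined", call. = FALSE)
  classified$totals[["piRNA"]] / tm
}

#' Per-family miRNA-normalized TE table for one library
#'
#' Aggregates TE alignment counts per family and strand, normalized per
#' million miRNAs.  Multi-placement reads are counted once per family (by
#' their strand-specific count mass at distinct placements collapsed to the
#' read level).
#'
#' @param alignments result of [map_library_to_panel()].
#' @param total_mirna the library's miRNA total.
#' @param library_id label for the output rows.
#' @return data.frame: `family`, `library_id`, `sense_rpm_mirna`,
#'   `antisense_rpm_mirna`, `total_rpm_mirna`, `pct_antisense`.
#' @export
te_family_table <- function(alignments, total_mirna, library_id = "lib1") {
  fams <- unique(alignments$family)
  ## one read may have several placements within a family; count it once
  per_fam <- lapply(fams, function(f) {
    a <- alignments[alignments$family == f, , drop = FALSE]
    key <- !duplicated(paste(a$sequence, a$strand))
    s <- sum(a$count[key & a$strand == "sense"])
    as <- sum(a$count[key & a$strand == "antisense"])
    data.frame(family = f, library_id = library_id,
               sense_rpm_mirna = normalize_per_million_mirna(s, total_mirna),
               antisense_rpm_mirna =
                 normalize_per_million_mirna(as, total_mirna),
               total_rpm_mirna =
                 normalize_per_million_mirna(s + as, total_mirna),
               pct_antisense = if (s + as > 0) 100 * as / (s + as) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_fam)
  rownames(out) <- NULL
  out
}

#' Log2 fold change of per-family TE abundance against a control library
#'
#' `log2((rpm_exp + eps_exp) / (rpm_ctrl + eps_ctrl))` with a pseudocount of
#' `pseudo_reads` reads (default 0.5) converted to each library's
#' miRNA-normalized scale: `eps = pseudo_reads * 1e6 / total_mirna`.
#'
#' @param table row-bound [te_family_table()] results for several libraries.
#' @param control_id `library_id` of the control column.
#' @param total_mirna named vector of miRNA totals per `library_id`.
#' @param pseudo_reads pseudocount in raw reads (default 0.5).
#' @param value which rpm column to compare (default `"total_rpm_mirna"`).
#' @return the table with a `log2_fold_change_vs_control` column.
#' @export
te_family_fold_change <- function(table, control_id, total_mirna,
                                  pseudo_reads = 0.5,
                                  value = "total_rpm_mirna") {
  if (!control_id %in% table$library_id)
    stop("control library not present in table", call. = FALSE)
  eps <- pseudo_reads * 1e6 / total_mirna
  ctrl <- table[table$library_id == control_id, , drop = FALSE]
  ctrl_v <- setNames(ctrl[[value]], ctrl$family)
  fc <- mapply(function(fam, libid, v) {
    cv <- ctrl_v[[fam]]
    if (is.null(cv) || is.na(cv)) return(NA_real_)
    log2((v + eps[[libid]]) / (cv + eps[[control_id]]))
  }, table$family, table$library_id, table[[value]])
  table$log2_fold_change_vs_control <- unname(fc)
  table
}
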