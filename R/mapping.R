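## Placement of reads on transposon consensus sequences (edit-tolerant, both
## strands) and on the genome (exact, both strands).
##
## A consensus placement is an anchored-start alignment: the read's 5'-most
## base is aligned (match or substitution) to the reported coordinate and
## gaps are internal, so every placement has a well-defined 5' position.
## Placements that are shifted shadows of a strictly better alignment
## (within max_edits positions on the same strand) are suppressed.

#' Match one read against a transposon consensus
#'
#' Finds all placements of `seq` on either strand of `consensus` with edit
#' (Levenshtein: substitutions + indels) cost at most `max_edits`, each
#' reduced to its strand, the consensus plus-strand coordinate of the read's
#' 5' nucleotide, and the edit cost.  For a sense placement the 5'
#' coordinate is the alignment start; for an antisense placement it is the
#' rightmost plus-strand base of the alignment.
#'
#' @param seq read sequence (>= 15 nt).
#' @param consensus consensus sequence.
#' @param max_edits maximal edit cost (default 2).
#' @return data.frame with columns `strand` (`"sense"`/`"antisense"`),
#'   `five_prime` (0-based) and `edits`; zero rows when there is no hit.
#' @export
#' @examples
#' cons <- strrep("ACGTTGCA", 10)
#' match_to_consensus(substring(cons, 11, 36), cons)
match_to_consensus <- function(seq, consensus, max_edits = 2L) {
  if (nchar(seq) < 15L) stop("read shorter than 15 nt", call. = FALSE)
  L <- nchar(consensus)
  fwd <- cpp_scan_anchored(seq, consensus, as.integer(max_edits))
  rev <- cpp_scan_anchored(seq, revcomp(consensus), as.integer(max_edits))
  out <- data.frame(
    strand = c(rep("sense", nrow(fwd)), rep("antisense", nrow(rev))),
    five_prime = c(fwd[, "pos"], L - 1L - rev[, "pos"]),
    edits = c(fwd[, "edits"], rev[, "edits"]),
    stringsAsFactors = FALSE)
  out <- out[order(out$strand, out$five_prime), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a library onto a transposon panel
#'
#' Every read is matched against all consensus sequences on both strands
#' with up to `max_edits` edits.  A read contributes alignments to every
#' family holding a placement at the read's global minimum edit cost
#' (best-hit set; ties count the read fully in each tied family).  With
#' `stratum = "best"` (default) only placements at that global minimum are
#' reported; `stratum = "all"` reports every placement with cost <=
#' `max_edits` in the tied families.
#'
#' @param lib a `smallrna_library`.
#' @param panel a `te_panel` (or named character vector of consensus).
#' @param max_edits maximal edit cost (default 2).
#' @param stratum `"best"` or `"all"`.
#' @return data.frame of TE alignments: `sequence`, `count`, `family`,
#'   `strand`, `five_prime`, `edits`.  Attribute `unmatched` holds the
#'   number of reads (count mass) without any placement.
#' @export
map_library_to_panel <- function(lib, panel, max_edits = 2L,
                                 stratum = c("best", "all")) {
  stratum <- match.arg(stratum)
  fams <- if (inherits(panel, "te_panel")) panel$families else
    unlist(panel)
  if (length(fams) == 0L) stop("panel has no families", call. = FALSE)
  rc_fams <- revcomp(fams)
  seqs <- lib$reads$sequence
  cnts <- lib$reads$count
  hits <- cpp_map_panel(seqs, unname(fams), unname(rc_fams),
                        as.integer(max_edits), stratum == "best")
  out <- data.frame(sequence = seqs[hits$read],
                    count = cnts[hits$read],
                    family = names(fams)[hits$family],
                    strand = c("sense", "antisense")[hits$strand + 1L],
                    five_prime = hits$five_prime,
                    edits = hits$edits,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmatched") <- sum(cnts) - sum(cnts[unique(hits$read)])
  out
}

#' Map a library onto the genome (exact, both strands)
#'
#' Enumerates every exact placement of every read on both genomic strands.
#' A read is flagged `unique` when it has exactly one placement genome-wide.
#' Reads with more placements than `max_hits` are dropped and logged.
#'
#' @param lib a `smallrna_library`.
#' @param panel a `te_panel` (or named character vector of chromosomes).
#' @param max_hits multiplicity cap (default 100).
#' @return data.frame of genome alignments: `sequence`, `count`, `chrom`,
#'   `strand` (`+`/`-`), `start` (0-based), `end` (exclusive), `unique`.
#'   Attributes: `unmapped` (count mass without any exact placement),
#'   `capped` (count mass dropped by `max_hits`).
#' @export
map_library_to_genome <- function(lib, panel, max_hits = 100L) {
  genome <- if (inherits(panel, "te_panel")) panel$genome else panel
  if (length(genome) == 0L) stop("genome is empty", call. = FALSE)
  seqs <- lib$reads$sequence
  cnts <- lib$reads$count
  if (length(seqs) == 0L)
    return(structure(data.frame(sequence = character(0), count = integer(0),
                                chrom = character(0), strand = character(0),
                                start = integer(0), end = integer(0),
                                unique = logical(0)),
                     unmapped = 0L, capped = 0L))
  widths <- nchar(seqs)
  chrom_seq <- lapply(genome, Biostrings::DNAString)
  chrom_rc <- lapply(chrom_seq, Biostrings::reverseComplement)
  hits <- list()
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    for (ch in names(genome)) {
      L <- nchar(genome[[ch]])
      for (str in c("+", "-")) {
        subj <- if (str == "+") chrom_seq[[ch]] else chrom_rc[[ch]]
        m <- Biostrings::matchPDict(pd, subj)
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0L) next
        ir <- unlist(m)
        who <- rep(idx, nh)
        st <- BiocGenerics::start(ir); en <- BiocGenerics::end(ir)
        if (str == "-") {  # map back to plus-strand coordinates
          tmp <- L - en + 1L
          en <- L - st + 1L
          st <- tmp
        }
        hits[[length(hits) + 1L]] <- data.frame(
          read = who, chrom = ch, strand = str,
          start = st - 1L, end = en, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(sequence = character(0), count = integer(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      unique = logical(0))
    attr(out, "unmapped") <- sum(cnts)
    attr(out, "capped") <- 0L
    return(out)
  }
  hits <- do.call(rbind, hits)
  mult <- tabulate(hits$read, nbins = length(seqs))
  capped_reads <- which(mult > max_hits)
  keep <- !(hits$read %in% capped_reads)
  hits <- hits[keep, , drop = FALSE]
  out <- data.frame(sequence = seqs[hits$read],
                    count = cnts[hits$read],
                    chrom = hits$chrom, strand = hits$strand,
                    start = hits$start, end = hits$end,
                    unique = mult[hits$read] == 1L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- sum(cnts[mult == 0L])
  attr(out, "capped") <- sum(cnts[capped_reads])
  out
}

#' Export TE alignments as TSV
#'
#' @param alignments result of [map_library_to_panel()].
#' @param path output path.
#' @export
write_te_alignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export genome alignments as BED6
#'
#' Name = sequence, score = count, strand as mapped.
#'
#' @param alignments result of [map_library_to_genome()].
#' @param path output path.
#' @export
write_genome_alignments_bed <- function(alignments, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = alignments$chrom,
    ranges = IRanges::IRanges(start = alignments$start + 1L,
                              end = alignments$end),
    strand = alignments$strand)
  names(gr) <- alignments$sequence
  gr$score <- alignments$count
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
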