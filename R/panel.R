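## Transposon panel: consensus sequences, a synthetic genome carrying them,
## and BED-style annotation intervals.

PANEL_CLASSES <- c("miRNA", "rRNA", "repeat", "cluster_unistrand",
                   "cluster_dualstrand", "other")

random_dna <- function(n) {
  paste(sample_int(DNA_BASES, n, replace = TRUE), collapse = "")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic transposon panel
#'
#' Builds a random reference: one consensus sequence per transposon family,
#' a genome in which every consensus is embedded at least once (annotated as
#' class `repeat`), a set of miRNA gene intervals, an rRNA interval, and one
#' uni-strand plus one dual-strand piRNA cluster interval.  The panel stands
#' in for a real consensus set, assembly and repeat/miRNA annotation so that
#' the downstream statistics can be validated against planted structure.
#'
#' @param n_families number of transposon families (>= 1).
#' @param consensus_len length range (two integers) for consensus sequences.
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in nt.
#' @param seed integer seed; the panel is byte-identical for a fixed seed.
#' @param n_mirna number of miRNA gene intervals.
#' @param mirna_len length of each miRNA gene interval.
#' @param rrna_len length of the rRNA interval.
#' @param cluster_len length of each piRNA cluster interval.
#' @return an object of class `te_panel`: list with `families` (named
#'   character), `genome` (named character), `annotation` (data.frame with
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `class`, `name`).
#' @export
#' @examples
#' panel <- generate_te_panel(2, consensus_len = c(300, 500),
#'                            n_chroms = 1, chrom_len = 20000, seed = 1)
#' table(panel$annotation$class)
generate_te_panel <- function(n_families, consensus_len = c(800, 1500),
                              n_chroms = 2, chrom_len = 50000, seed = 1,
                              n_mirna = 10, mirna_len = 80,
                              rrna_len = 1500, cluster_len = 8000) {
  stopifnot(n_families >= 1, length(consensus_len) %in% c(1L, 2L))
  consensus_len <- as.integer(rep(consensus_len, length.out = 2L))
  if (any(consensus_len < 100) || chrom_len < 100)
    stop("consensus and chromosome lengths must be >= 100", call. = FALSE)

  with_seed(seed, {
    fam_len <- if (consensus_len[1] == consensus_len[2]) {
      rep(consensus_len[1], n_families)
    } else {
      sample(seq(consensus_len[1], consensus_len[2]), n_families,
             replace = TRUE)
    }
    families <- vapply(fam_len, random_dna, character(1))
    names(families) <- sprintf("TE%02d", seq_len(n_families))

    genome <- vapply(rep(chrom_len, n_chroms), random_dna, character(1))
    names(genome) <- sprintf("chr%d", seq_len(n_chroms))

    ## features to place, in order: one repeat insertion per family, the
    ## miRNA genes, the rRNA locus, and the two clusters
    feat <- data.frame(
      class = c(rep("repeat", n_families), rep("miRNA", n_mirna), "rRNA",
                "cluster_unistrand", "cluster_dualstrand"),
      name = c(names(families), sprintf("mir-%d", seq_len(n_mirna)),
               "rRNA-1", "cluster-uni", "cluster-dual"),
      len = c(fam_len, rep(mirna_len, n_mirna), rrna_len,
              cluster_len, cluster_len),
      stringsAsFactors = FALSE)

    ann <- vector("list", nrow(feat))
    chrom_i <- 1L
    pos <- 0L
    for (k in seq_len(nrow(feat))) {
      gap <- sample(50:200, 1L)
      start <- pos + gap
      end <- start + feat$len[k]
      while (end > chrom_len) {
        chrom_i <- chrom_i + 1L
        if (chrom_i > n_chroms)
          stop("chrom_len too small to host the requested features; ",
               "increase chrom_len or n_chroms", call. = FALSE)
        start <- sample(50:200, 1L)
        end <- start + feat$len[k]
      }
      chrom <- names(genome)[chrom_i]
      if (feat$class[k] == "repeat") {
        seqs <- families[[feat$name[k]]]
        substr(genome[[chrom]], start + 1L, end) <- seqs
      }
      ann[[k]] <- data.frame(chrom = chrom, start = as.integer(start),
                             end = as.integer(end),
                             strand = "+", class = feat$class[k],
                             name = feat$name[k], stringsAsFactors = FALSE)
      pos <- end
    }
    annotation <- do.call(rbind, ann)
    structure(list(families = families, genome = genome,
                   annotation = annotation, seed = as.integer(seed)),
              class = "te_panel")
  })
}

#' @export
print.te_panel <- function(x, ...) {
  cat("Transposon panel:", length(x$families), "families,",
      length(x$genome), "chromosomes\n")
  cat("  consensus lengths:", paste(nchar(x$families), collapse = ", "), "\n")
  cat("  annotation intervals by class:\n")
  print(table(x$annotation$class))
  invisible(x)
}

#' Annotation intervals as a GRanges object
#'
#' @param annotation the `annotation` data.frame of a [generate_te_panel()]
#'   panel (or any data.frame with the same columns).
#' @return a [GenomicRanges::GRanges] with `class` and `name` metadata
#'   columns (coordinates converted to 1-based closed).
#' @export
annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand,
    class = annotation$class,
    name = annotation$name)
}

#' Write a panel to FASTA + BED6 files
#'
#' Consensus and genome sequences are written as FASTA; the annotation as
#' BED6 with the name field `class|name`.
#'
#' @param panel a `te_panel`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("consensus.fa", "genome.fa", "annotation.bed"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$families),
                              paths[1])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$genome),
                              paths[2])
  gr <- annotation_granges(panel$annotation)
  gr$name <- paste(gr$class, gr$name, sep = "|")
  gr$class <- NULL
  rtracklayer::export(gr, paths[3], format = "BED")
  invisible(paths)
}

#' Read a panel back from FASTA + BED6 files
#'
#' @param consensus_fasta,genome_fasta,annotation_bed paths as written by
#'   [write_panel()].
#' @return a `te_panel`.
#' @export
read_te_panel <- function(consensus_fasta, genome_fasta, annotation_bed) {
  fam <- Biostrings::readDNAStringSet(consensus_fasta)
  gen <- Biostrings::readDNAStringSet(genome_fasta)
  gr <- rtracklayer::import(annotation_bed, format = "BED")
  nm <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  annotation <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = vapply(nm, `[`, character(1), 1L),
    name = vapply(nm, `[`, character(1), 2L),
    stringsAsFactors = FALSE)
  annotation$strand[annotation$strand == "*"] <- "+"
  structure(list(families = setNames(as.character(fam), names(fam)),
                 genome = setNames(as.character(gen), names(gen)),
                 annotation = annotation, seed = NA_integer_),
            class = "te_panel")
}
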