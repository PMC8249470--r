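# Classification, normalization and fold-change bookkeeping on a hand-built
# genome whose annotation intervals are fully known.
local({
  set.seed(23)
  chr <- random_dna_str(3000)
  ann <- data.frame(
    chrom = "chr1",
    start = c(100L, 500L, 900L),
    end = c(200L, 700L, 1100L),
    strand = "+",
    class = c("miRNA", "rRNA", "repeat"),
    name = c("mir-1", "rRNA-1", "TE01"))
  genome <- c(chr1 = chr)
  read_at <- function(start0, len) substring(chr, start0 + 1, start0 + len)

  test_that("classification follows the miRNA > rRNA > piRNA > other priority", {
    reads <- c(mir = read_at(120, 22),     # miRNA gene, 22 nt
               rep25 = read_at(950, 25),   # repeat, piRNA-sized
               rep22 = read_at(950, 22),   # repeat but too short for piRNA
               rrna = read_at(550, 25),    # rRNA even at piRNA size
               none = strrep("AG", 13))    # no genomic placement
    lib <- toy_library(unname(reads), c(1L, 2L, 3L, 4L, 5L))
    gal <- map_library_to_genome(lib, genome)
    cls <- classify_reads(lib, gal, ann)
    got <- setNames(cls$reads$class, cls$reads$sequence)
    expect_identical(unname(got[reads["mir"]]), "miRNA")
    expect_identical(unname(got[reads["rep25"]]), "piRNA")
    expect_identical(unname(got[reads["rep22"]]), "other")
    expect_identical(unname(got[reads["rrna"]]), "rRNA")
    expect_identical(unname(got[reads["none"]]), "other")
    ## class totals partition the library exactly
    expect_equal(sum(cls$totals), sum(lib$reads$count))
  })

  test_that("a read overlapping both a miRNA gene and a repeat is miRNA", {
    ann2 <- rbind(ann, data.frame(chrom = "chr1", start = 100L, end = 200L,
                                  strand = "+", class = "repeat",
                                  name = "TE98"))
    lib <- toy_library(read_at(120, 25), 1L)
    gal <- map_library_to_genome(lib, genome)
    cls <- classify_reads(lib, gal, ann2)
    expect_identical(cls$reads$class, "miRNA")
  })

  test_that("piRNA:miRNA ratio reproduces the control-like 2:1 anchor", {
    reads <- c(read_at(120, 22), read_at(950, 25), read_at(980, 26))
    lib <- toy_library(reads, c(100L, 150L, 50L))
    gal <- map_library_to_genome(lib, genome)
    cls <- classify_reads(lib, gal, ann)
    expect_equal(pirna_mirna_ratio(cls), 2.0)
    expect_equal(cls$totals[["piRNA"]] / cls$totals[["miRNA"]], 2.0)
  })

  test_that("length distributions are count-weighted and conserve class totals", {
    reads <- c(read_at(950, 25), read_at(980, 25), read_at(1000, 26))
    lib <- toy_library(reads, c(2L, 1L, 1L))
    gal <- map_library_to_genome(lib, genome)
    cls <- classify_reads(lib, gal, ann)
    ld <- length_distribution(cls, classes = "piRNA")
    expect_identical(unname(ld["25", "piRNA"]), 3)
    expect_identical(unname(ld["26", "piRNA"]), 1)
    expect_identical(sum(ld[, "piRNA"]), unname(cls$totals[["piRNA"]]))
    expect_true(all(length_distribution(cls, classes = "other") == 0))
  })
})

test_that("miRNA-normalized rpm follows the stated formula and scale invariance", {
  expect_equal(normalize_per_million_mirna(50, 1e5), 500)
  expect_equal(normalize_per_million_mirna(0, 1e6), 0)
  expect_equal(normalize_per_million_mirna(5, 1e6), 5)  # window threshold
  expect_error(normalize_per_million_mirna(1, 0), "positive")
  ## linear in count; joint scaling leaves rpm unchanged
  k <- 7
  expect_equal(normalize_per_million_mirna(k * 13, 1e5),
               k * normalize_per_million_mirna(13, 1e5))
  expect_equal(normalize_per_million_mirna(13 * k, 1e5 * k),
               normalize_per_million_mirna(13, 1e5))
})

test_that("total-RPM normalization discards rRNA from the denominator by contract", {
  expect_equal(normalize_rpm_total(10, 1e6), 10)
  expect_equal(normalize_rpm_total(10, 2e6), 5)
  expect_equal(normalize_rpm_total(0, 1), 0)
  expect_error(normalize_rpm_total(1, 0), "positive")
})

test_that("fold changes use the symmetric 0.5-read pseudocount", {
  tab <- data.frame(
    family = rep(c("TE01", "TE02", "TE03"), 2),
    library_id = rep(c("ctrl", "exp"), each = 3),
    total_rpm_mirna = c(10, 4, 0, 5, 4, 0))
  tm <- c(ctrl = 1e6, exp = 1e6)   # eps = 0.5 rpm in both
  fc <- te_family_fold_change(tab, "ctrl", tm)
  got <- fc[fc$library_id == "exp", ]
  expect_equal(got$log2_fold_change_vs_control[got$family == "TE01"],
               log2(5.5 / 10.5))
  expect_equal(got$log2_fold_change_vs_control[got$family == "TE02"], 0)
  expect_equal(got$log2_fold_change_vs_control[got$family == "TE03"], 0)
  expect_true(all(fc$log2_fold_change_vs_control[fc$library_id ==
                                                   "ctrl"] == 0))
  expect_error(te_family_fold_change(tab, "missing", tm), "control")
})

test_that("te_family_table counts multi-placement reads once per family/strand", {
  aln <- data.frame(
    sequence = c("s1", "s1", "s2"), count = c(4L, 4L, 6L),
    family = "TE01", strand = c("sense", "sense", "antisense"),
    five_prime = c(10L, 50L, 30L), edits = 0L)
  tab <- te_family_table(aln, total_mirna = 1e6, library_id = "lib")
  expect_equal(tab$sense_rpm_mirna, 4)       # s1 once despite 2 placements
  expect_equal(tab$antisense_rpm_mirna, 6)
  expect_equal(tab$pct_antisense, 60)
})
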