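test_that("window tiling truncates the last tile and never spans chromosomes", {
  w <- make_windows(c(chr1 = 12000), size = 5000)
  expect_identical(w$start, c(0L, 5000L, 10000L))
  expect_identical(w$end, c(5000L, 10000L, 12000L))
  w1 <- make_windows(c(chr1 = 1000), size = 1000)
  expect_identical(nrow(w1), 1L)
  w2 <- make_windows(c(chr1 = 7000, chr2 = 3000), size = 5000)
  expect_identical(w2$chrom, c("chr1", "chr1", "chr2"))
  expect_true(all(w2$end <= c(5000, 7000, 3000)))
  expect_error(make_windows(c(chr1 = 1000), size = 10), "size")
})

test_that("reads land in the window holding their 5' end, minus strand included", {
  gal <- data.frame(
    sequence = c("a", "b", "c"), count = c(1L, 2L, 4L),
    chrom = "chr1", strand = c("+", "-", "-"),
    start = c(7000L, 4998L, 4970L), end = c(7026L, 5024L, 4996L),
    unique = TRUE)
  w <- make_windows(c(chr1 = 10000), 5000)
  wc <- window_counts(gal, w, total_mirna = 1e6)
  ## + read at 7000 and the boundary-spanning - read (5' = 5023) go to
  ## [5000,10000); the - read with 5' = 4995 goes to [0,5000)
  expect_equal(wc$count, c(4, 3))
  expect_equal(wc$rpm_mirna, c(4, 3))
  ## non-unique placements are excluded by default but kept on request
  gal$unique[1] <- FALSE
  expect_equal(window_counts(gal, w, 1e6)$count, c(4, 2))
  expect_equal(window_counts(gal, w, 1e6, unique_only = FALSE)$count,
               c(4, 3))
})

test_that("window counting conserves total placement mass", {
  set.seed(41)
  n <- 200
  gal <- data.frame(
    sequence = sprintf("r%03d", 1:n), count = sample(1:9, n, TRUE),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    start = sample(0:11950, n, TRUE))
  gal$end <- gal$start + 26L
  gal$unique <- TRUE
  w <- make_windows(c(chr1 = 12000, chr2 = 12000), 5000)
  wc <- window_counts(gal, w, 1e6, unique_only = FALSE)
  expect_equal(sum(wc$count), sum(gal$count))
})

test_that("the control/reduction filters keep exactly the qualifying windows", {
  tab <- data.frame(chrom = "chr1", start = c(0L, 5000L, 10000L),
                    end = c(5000L, 10000L, 15000L),
                    rpm.ctrl = c(6, 4, 10), rpm.mut = c(1, 0.1, 9))
  out <- filter_windows(tab, "ctrl", "mut")
  expect_identical(nrow(out), 1L)            # only [6 -> 1]: 83% reduction
  expect_equal(out$rpm.ctrl, 6)
  ## boundaries: control = 5.0 is kept ("at least 5"); reduction exactly
  ## 80% is dropped ("more than 80%")
  tab2 <- data.frame(rpm.ctrl = c(5, 10), rpm.mut = c(0.5, 2))
  out2 <- filter_windows(tab2, "ctrl", "mut")
  expect_identical(nrow(out2), 1L)
  expect_equal(out2$rpm.ctrl, 5)
  expect_error(filter_windows(tab2, "ctrl", "nope"), "missing")
})

test_that("raising either filter threshold never adds survivors", {
  set.seed(43)
  tab <- data.frame(rpm.ctrl = runif(200, 0, 20), rpm.mut = runif(200, 0, 20))
  base <- filter_windows(tab, "ctrl", "mut", min_rpm = 5,
                         min_reduction = 0.8)
  for (args in list(list(min_rpm = 8, min_reduction = 0.8),
                    list(min_rpm = 5, min_reduction = 0.9),
                    list(min_rpm = 8, min_reduction = 0.9))) {
    tighter <- filter_windows(tab, "ctrl", "mut", min_rpm = args$min_rpm,
                              min_reduction = args$min_reduction)
    expect_true(all(rownames(tighter) %in% rownames(base)) ||
                  nrow(tighter) <= nrow(base))
  }
})

test_that("cluster fold changes cover only cluster windows with the pseudocount", {
  ann <- data.frame(chrom = "chr1", start = 2000L, end = 6000L,
                    strand = "+", class = "cluster_dualstrand",
                    name = "cl-1")
  tab <- data.frame(chrom = "chr1", start = seq(0L, 9000L, 1000L),
                    end = seq(1000L, 10000L, 1000L))
  tab$rpm.ctrl <- c(0, 0, 10, 10, 20, 40, 0, 0, 5, 5)
  tab$rpm.exp <- c(0, 0, 10, 5, 40, 40, 0, 0, 5, 5)
  attr(tab, "total_mirna") <- c(ctrl = 1e6, exp = 1e6)
  fc <- cluster_fold_change(tab, ann, "ctrl")
  expect_identical(nrow(fc), 4L)               # windows [2000,6000)
  expect_true(all(fc$cluster == "cl-1"))
  expect_equal(fc$log2fc.exp[fc$start == 2000], 0)
  expect_equal(fc$log2fc.exp[fc$start == 4000], log2(40.5 / 20.5))
  expect_error(cluster_fold_change(tab, ann[0, ], "ctrl"), "cluster")
})

test_that("planted cluster reductions are visible per window and uni-strand clusters never pass", {
  panel <- shared_panel()
  r <- 0.15
  mk <- function(geno, red, seed)
    simulate_library(panel,
                     library_params(genotype = geno, n_pirna_pairs = 0,
                                    n_mirna_reads = 2000,
                                    n_cluster_reads = 4000,
                                    reduction_factor = red,
                                    seed = seed))$library
  ctrl <- mk("ctrl", 1, 51)
  mut <- mk("mut", r, 52)
  w <- make_windows(panel, 1000)
  cols <- lapply(list(ctrl = ctrl, mut = mut), function(lib) {
    gal <- map_library_to_genome(lib, panel)
    cls <- classify_reads(lib, gal, panel$annotation)
    keep <- cls$reads$sequence[cls$reads$class != "miRNA" &
                                 cls$reads$length >= 23]
    window_counts(gal[gal$sequence %in% keep, ], w, cls$totals[["miRNA"]],
                  size = 1000)
  })
  tab <- window_table(cols, c(ctrl = 2000, mut = 2000))
  ann <- panel$annotation
  dual <- ann[ann$class == "cluster_dualstrand", ]
  uni <- ann[ann$class == "cluster_unistrand", ]
  in_iv <- function(iv) tab$chrom == iv$chrom & tab$start >= iv$start &
    tab$end <= iv$end
  covered <- in_iv(dual) & tab$rpm.ctrl > 0
  red <- (tab$rpm.ctrl[covered] - tab$rpm.mut[covered]) /
    tab$rpm.ctrl[covered]
  ## mean per-window reduction tracks 1 - r
  expect_lt(abs(mean(red) - (1 - r)), 0.1)
  ## uni-strand cluster windows (reduction factor 1) never pass the filter
  surv <- filter_windows(tab, "ctrl", "mut")
  uni_surv <- surv$chrom == uni$chrom & surv$start >= uni$start -
    999 & surv$end <= uni$end + 999
  expect_identical(sum(uni_surv), 0L)
})
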