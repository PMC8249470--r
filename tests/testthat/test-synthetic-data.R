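test_that("panel construction places every feature class and is seed-stable", {
  panel <- generate_te_panel(2, consensus_len = c(300, 500), n_chroms = 1,
                             chrom_len = 50000, seed = 1)
  expect_length(panel$families, 2)
  ann <- panel$annotation
  expect_gte(sum(ann$class == "repeat"), 2)
  expect_gte(sum(ann$class == "miRNA"), 1)
  expect_gte(sum(ann$class == "cluster_unistrand"), 1)
  expect_gte(sum(ann$class == "cluster_dualstrand"), 1)
  expect_true(all(ann$start >= 0 & ann$start < ann$end))
  expect_true(all(ann$end <= nchar(panel$genome[ann$chrom])))
  ## each consensus is embedded verbatim at its repeat interval
  for (f in names(panel$families)) {
    iv <- ann[ann$class == "repeat" & ann$name == f, ][1, ]
    expect_identical(substring(panel$genome[[iv$chrom]], iv$start + 1, iv$end),
                     panel$families[[f]])
  }
  expect_identical(panel,
                   generate_te_panel(2, consensus_len = c(300, 500),
                                     n_chroms = 1, chrom_len = 50000,
                                     seed = 1))
})

test_that("panel generation fails when the chromosome cannot host the features", {
  expect_error(generate_te_panel(1, consensus_len = c(300, 300),
                                 n_chroms = 1, chrom_len = 100, seed = 1),
               "too small|>= 100")
})

test_that("simulated libraries are bit-reproducible and truth totals are exact", {
  panel <- shared_panel()
  p <- library_params(n_pirna_pairs = 500, n_mirna_reads = 300,
                      n_rrna_reads = 50, n_cluster_reads = 100, seed = 11)
  sim1 <- simulate_library(panel, p)
  sim2 <- simulate_library(panel, p)
  expect_identical(sim1$library$reads, sim2$library$reads)
  expect_identical(sim1$truth, sim2$truth)
  ## realized totals equal recomputed sums over the emitted library
  expect_identical(sum(sim1$library$reads$count),
                   as.integer(sim1$truth$totals[["all"]]))
  expect_identical(as.integer(sim1$truth$totals[["te_pirna"]]),
                   2L * sim1$truth$n_events)
})

test_that("a pure-miRNA library has no piRNA signal", {
  panel <- shared_panel()
  p <- library_params(n_pirna_pairs = 0, n_mirna_reads = 400,
                      n_rrna_reads = 0, n_cluster_reads = 0, seed = 3)
  sim <- simulate_library(panel, p)
  gal <- map_library_to_genome(sim$library, panel)
  cls <- classify_reads(sim$library, gal, panel$annotation)
  expect_identical(unname(cls$totals[["piRNA"]]), 0)
  expect_equal(pirna_mirna_ratio(cls), 0)
})

test_that("every planted responder overlaps its initiator by exactly 10 nt", {
  panel <- shared_panel()
  p <- library_params(n_pirna_pairs = 400, p_pingpong = 1,
                      p_1U_antisense = 0.6, p_10A_sense = 0.6,
                      n_mirna_reads = 0, n_rrna_reads = 0,
                      n_cluster_reads = 0, seed = 5)
  sim <- simulate_library(panel, p)
  aln <- map_library_to_panel(sim$library, panel)
  h <- combined_histogram(aln)
  expect_equal(h$pingpong_fraction, 100, tolerance = 1e-9)
})

test_that("requested bias marginals are honoured by the emitted reads", {
  panel <- shared_panel()
  p <- library_params(n_pirna_pairs = 20000, p_pingpong = 0.5,
                      p_1U_antisense = 0.75, p_10A_sense = 0.47, seed = 17)
  t <- simulate_library(panel, p)$truth
  ## event-level binomial: 3 sigma on 20k draws
  expect_lt(abs(t$frac_1U_antisense - 0.75), 3 * sqrt(0.75 * 0.25 / 20000))
  expect_lt(abs(t$frac_10A_sense - 0.47), 3 * sqrt(0.47 * 0.53 / 20000))
})

test_that("incompatible bias requests are rejected with the geometric reason", {
  panel <- shared_panel()
  expect_error(library_params(p_pingpong = 0.9, p_1U_antisense = 0.9,
                              p_10A_sense = 0.2) |>
                 (\(p) simulate_library(panel, p))(),
               "geometrically infeasible")
})

test_that("uniform positioning with no planted pairs gives no offset-10 peak", {
  panel <- shared_panel()
  ratios <- vapply(1:20, function(s) {
    p <- library_params(n_pirna_pairs = 600, p_pingpong = 0,
                        n_mirna_reads = 0, n_rrna_reads = 0,
                        n_cluster_reads = 0, positioning = "uniform",
                        seed = s)
    sim <- simulate_library(panel, p)
    aln <- map_library_to_panel(sim$library, panel)
    h <- combined_histogram(aln)
    h$values[["10"]] / mean(h$values)
  }, numeric(1))
  expect_true(all(ratios <= 3))
})

test_that("parameter validation rejects malformed length distributions and counts", {
  expect_error(library_params(pirna_length_dist = c(`22` = 1)), "lengths")
  expect_error(library_params(pirna_length_dist = c(`23` = 0.4, `24` = 0.4)),
               "sum to 1")
  expect_error(library_params(n_pirna_pairs = -1), ">= 0")
  expect_error(library_params(p_pingpong = 1.2), "probability")
})

test_that("panel and truth round-trip through their file formats", {
  panel <- generate_te_panel(2, consensus_len = c(300, 400), n_chroms = 1,
                             chrom_len = 30000, seed = 9)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  back <- read_te_panel(file.path(dir, "consensus.fa"),
                        file.path(dir, "genome.fa"),
                        file.path(dir, "annotation.bed"))
  expect_identical(back$families, panel$families)
  expect_identical(back$genome, panel$genome)
  expect_identical(back$annotation[order(back$annotation$start), ]$start,
                   panel$annotation[order(panel$annotation$start), ]$start)
  expect_setequal(back$annotation$class, panel$annotation$class)

  p <- library_params(n_pirna_pairs = 50, seed = 2)
  sim <- simulate_library(panel, p)
  truth_path <- file.path(dir, "truth.json")
  write_truth(sim$truth, truth_path)
  truth <- jsonlite::read_json(truth_path)
  expect_equal(truth$n_events, sim$truth$n_events)
  expect_equal(truth$frac_10A_sense, sim$truth$frac_10A_sense,
               tolerance = 1e-12)
})
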