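test_that("exact substrings and reverse-complement reads are placed correctly", {
  set.seed(2)
  cons <- random_dna_str(120)
  m <- match_to_consensus(substring(cons, 11, 36), cons)
  expect_identical(m, data.frame(strand = "sense", five_prime = 10L,
                                 edits = 0L))
  ## 5' of a minus-strand read is the rightmost plus-strand base: 40+26-1=65
  m2 <- match_to_consensus(revcomp(substring(cons, 41, 66)), cons)
  expect_identical(m2$strand, "antisense")
  expect_identical(m2$five_prime, 65L)
  expect_identical(m2$edits, 0L)
  ## three substitutions exceed the edit budget
  s <- substring(cons, 11, 36)
  for (i in c(3, 10, 20))
    s <- mutate_at(s, i, setdiff(c("A", "C", "G", "T"),
                                 substring(s, i, i))[1])
  expect_identical(nrow(match_to_consensus(s, cons)), 0L)
  expect_error(match_to_consensus("ACGTACGTACGT", cons), "shorter than 15")
})

test_that("substitutions and indels within the budget are found with their cost", {
  set.seed(3)
  cons <- random_dna_str(200)
  s <- substring(cons, 51, 76)
  s1 <- mutate_at(s, 12, setdiff(c("A", "C", "G", "T"),
                                 substring(s, 12, 12))[1])
  m <- match_to_consensus(s1, cons)
  hit <- m[m$five_prime == 50 & m$strand == "sense", ]
  expect_identical(hit$edits, 1L)
  ## internal deletion of one read base: still anchored at 50
  s2 <- paste0(substring(s, 1, 11), substring(s, 13, 26))
  m2 <- match_to_consensus(s2, cons)
  expect_true(any(m2$five_prime == 50 & m2$edits == 1L &
                    m2$strand == "sense"))
})

test_that("the scanner agrees exactly with a naive per-start oracle", {
  set.seed(7)
  n_cases <- 1000
  for (case in seq_len(n_cases)) {
    cons <- random_dna_str(300)
    read <- if (case %% 2 == 0) {
      random_dna_str(26)                      # mostly no hit
    } else {                                  # planted mutated substring
      st <- sample(1:270, 1)
      s <- substring(cons, st, st + 25)
      n_mut <- sample(0:3, 1)
      for (i in sample(2:25, n_mut))
        s <- mutate_at(s, i, sample(c("A", "C", "G", "T"), 1))
      if (sample(c(TRUE, FALSE), 1)) revcomp(s) else s
    }
    got <- match_to_consensus(read, cons, max_edits = 2)
    want <- oracle_match(read, cons, max_edits = 2)
    expect_equal(unname(as.matrix(got[c("five_prime", "edits")])),
                 unname(as.matrix(want[c("five_prime", "edits")])),
                 info = sprintf("case %d", case))
    expect_identical(got$strand, want$strand,
                     info = sprintf("case %d strands", case))
  }
})

test_that("reverse-complementing the consensus swaps strands and reflects 5' ends", {
  set.seed(11)
  for (case in 1:40) {
    cons <- random_dna_str(250)
    st <- sample(1:220, 1)
    s <- substring(cons, st, st + 25)
    if (case %% 2 == 0) s <- revcomp(s)
    if (case %% 3 == 0) s <- mutate_at(s, sample(3:24, 1), "A")
    L <- nchar(cons)
    a <- match_to_consensus(s, cons)
    b <- match_to_consensus(s, revcomp(cons))
    swap <- data.frame(
      strand = ifelse(b$strand == "sense", "antisense", "sense"),
      five_prime = L - 1L - b$five_prime,
      edits = b$edits)
    swap <- swap[order(swap$strand, swap$five_prime), , drop = FALSE]
    expect_identical(a$strand, swap$strand, info = sprintf("case %d", case))
    expect_identical(a$five_prime, swap$five_prime,
                     info = sprintf("case %d", case))
    expect_identical(a$edits, swap$edits, info = sprintf("case %d", case))
  }
})

test_that("family assignment follows the best-hit rule with full tie counting", {
  set.seed(13)
  A <- random_dna_str(300)
  B <- random_dna_str(300)
  read_exact_A <- substring(A, 101, 126)
  ## plant a 2-edit copy of that read inside B
  other <- function(s, i) setdiff(c("A", "C", "G", "T"),
                                  substring(s, i, i))[1]
  copy <- mutate_at(read_exact_A, 5, other(read_exact_A, 5))
  copy <- mutate_at(copy, 15, other(copy, 15))
  B2 <- paste0(substring(B, 1, 50), copy, substring(B, 77, 300))
  panel2 <- list(TEa = A, TEb = B2)
  lib <- toy_library(read_exact_A, 4L)
  aln <- map_library_to_panel(lib, panel2, max_edits = 2)
  expect_identical(unique(aln$family), "TEa")

  ## exact in both families: alignments to both, counts carried unchanged
  B3 <- paste0(substring(B, 1, 50), read_exact_A, substring(B, 77, 300))
  aln2 <- map_library_to_panel(lib, list(TEa = A, TEb = B3), max_edits = 2)
  expect_setequal(aln2$family, c("TEa", "TEb"))
  expect_true(all(aln2$count == 4L))

  ## unmatched read mass is reported
  lib2 <- toy_library(c(read_exact_A, strrep("ACGT", 7)), c(1L, 9L))
  aln3 <- map_library_to_panel(lib2, list(TEa = A), max_edits = 0)
  expect_identical(attr(aln3, "unmatched"), 9L)
})

test_that("stratum='all' keeps suboptimal placements within best families", {
  set.seed(17)
  A <- random_dna_str(400)
  read <- substring(A, 101, 126)
  ## plant a 1-edit copy elsewhere in the same family
  copy <- mutate_at(read, 13, setdiff(c("A", "C", "G", "T"),
                                      substring(read, 13, 13))[1])
  A2 <- paste0(substring(A, 1, 300), copy, substring(A, 327, 400))
  lib <- toy_library(read, 1L)
  best <- map_library_to_panel(lib, list(TEa = A2), max_edits = 2)
  expect_true(all(best$edits == 0L))
  all_hits <- map_library_to_panel(lib, list(TEa = A2), max_edits = 2,
                                   stratum = "all")
  expect_true(any(all_hits$edits == 1L))
  expect_gt(nrow(all_hits), nrow(best))
})

test_that("genome mapping enumerates exact placements and flags uniqueness", {
  set.seed(19)
  chr <- random_dna_str(5000)
  once <- substring(chr, 1001, 1026)
  dup <- random_dna_str(26)
  chr <- paste0(chr, dup, random_dna_str(100), dup)
  genome <- c(chr1 = chr)
  lib <- toy_library(c(once, dup, revcomp(once), strrep("AC", 13)),
                     c(1L, 2L, 3L, 4L))
  gal <- map_library_to_genome(lib, genome)
  g1 <- gal[gal$sequence %in% c(once, revcomp(once)), ]
  ## the forward read and its reverse complement hit the same locus on
  ## opposite strands
  expect_setequal(g1$strand, c("+", "-"))
  expect_true(all(g1$start == 1000L & g1$end == 1026L))
  expect_true(all(g1$unique))
  g2 <- gal[gal$sequence == dup, ]
  expect_identical(nrow(g2), 2L)
  expect_false(any(g2$unique))
  expect_identical(attr(gal, "unmapped"), 4L)
})

test_that("the genome multiplicity cap drops repetitive reads with a logged mass", {
  seed_unit <- strrep("ACGT", 7)
  genome <- c(chr1 = strrep(seed_unit, 60))
  lib <- toy_library(seed_unit, 5L)
  gal <- map_library_to_genome(lib, genome, max_hits = 10)
  expect_identical(nrow(gal), 0L)
  expect_identical(attr(gal, "capped"), 5L)
})
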