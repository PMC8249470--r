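# Independent oracles and random-case generators shared across tests.

# Naive reference for the anchored consensus scan.  For every start
# position, the anchored distance is the first-base match cost plus the
# minimum Levenshtein distance (via utils::adist, an independent C
# implementation) between the read remainder and the subject prefixes whose
# length is within max_edits of the remainder; the same shadow-suppression
# rule as the scanner is then applied.
oracle_scan <- function(read, subject, max_edits = 2L) {
  m <- nchar(read)
  L <- nchar(subject)
  rest <- substring(read, 2L)
  na <- m - 1L
  hits_pos <- integer(0)
  hits_ed <- integer(0)
  for (s0 in 0:(L - 1L)) {
    if (s0 + (m - max_edits) > L) next
    c0 <- as.integer(substring(read, 1L, 1L) != substring(subject, s0 + 1L,
                                                          s0 + 1L))
    if (c0 > max_edits) next
    d_rest <- if (na == 0L) 0L else {
      es <- max(0L, na - max_edits):min(L - s0 - 1L, na + max_edits)
      prefixes <- substring(subject, s0 + 2L, s0 + 1L + es)
      min(utils::adist(rest, prefixes))
    }
    d <- c0 + d_rest
    if (d <= max_edits) {
      hits_pos <- c(hits_pos, s0)
      hits_ed <- c(hits_ed, d)
    }
  }
  keep <- vapply(seq_along(hits_pos), function(u) {
    !any(hits_ed < hits_ed[u] & abs(hits_pos - hits_pos[u]) <= max_edits)
  }, logical(1))
  data.frame(pos = hits_pos[keep], edits = hits_ed[keep])
}

# Reference for match_to_consensus on both strands.
oracle_match <- function(seq, consensus, max_edits = 2L) {
  L <- nchar(consensus)
  fwd <- oracle_scan(seq, consensus, max_edits)
  rev <- oracle_scan(seq, revcomp(consensus), max_edits)
  out <- data.frame(
    strand = c(rep("sense", nrow(fwd)), rep("antisense", nrow(rev))),
    five_prime = c(fwd$pos, L - 1L - rev$pos),
    edits = c(fwd$edits, rev$edits))
  out[order(out$strand, out$five_prime), , drop = FALSE]
}

# Brute-force combined ping-pong histogram: explicit per-target enumeration
# of opposite-strand partners, per-target normalization to 100%, and
# count-proportional weighting over partnered targets.
oracle_histogram <- function(aln) {
  numer <- numeric(29)
  denom <- 0
  for (t in seq_len(nrow(aln))) {
    opp <- aln$family == aln$family[t] & aln$strand != aln$strand[t]
    if (!any(opp)) next
    o <- if (aln$strand[t] == "sense")
      aln$five_prime[opp] - aln$five_prime[t] + 1L
    else
      aln$five_prime[t] - aln$five_prime[opp] + 1L
    ok <- o >= 1L & o <= 29L
    if (!any(ok)) next
    h <- vapply(1:29, function(k) sum(aln$count[opp][ok & o == k]),
                numeric(1))
    numer <- numer + aln$count[t] * 100 * h / sum(h)
    denom <- denom + aln$count[t]
  }
  if (denom == 0) rep(NA_real_, 29) else numer / denom
}

# Random alignment tables for property tests.
random_alignments <- function(n, n_fam = 2L, pos_range = 60L) {
  data.frame(
    sequence = sprintf("read%03d", seq_len(n)),
    count = sample(1:20, n, replace = TRUE),
    family = sprintf("TE%02d", sample.int(n_fam, n, replace = TRUE)),
    strand = sample(c("sense", "antisense"), n, replace = TRUE),
    five_prime = sample.int(pos_range, n, replace = TRUE) - 1L,
    edits = 0L,
    stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

# Small shared panel for expensive fixtures (built once per test run).
shared_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) panel <<- generate_te_panel(4, seed = 42)
    panel
  }
})

# A tiny deterministic library over explicit read tables.
toy_library <- function(seqs, counts, id = "toy") {
  smallrna_library(data.frame(sequence = seqs, count = counts),
                   library_id = id)
}
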