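## Synthetic small RNA library generator with planted ping-pong structure.
##
## The geometry of a ping-pong pair makes the responder's position-10 base
## the complement of the initiator's first base: both map to the same
## consensus base.  The generator therefore solves for three subpopulation
## rates -- the shared coin q for planted pairs, q_a for initiators without a
## responder and q_s for non-responder sense reads -- such that the marginal
## 1U fraction among antisense reads and the marginal 10A fraction among
## sense reads both equal the requested values.  This is feasible iff
## |p_1U_antisense - p_10A_sense| <= 1 - p_pingpong.

#' Parameters for a simulated small RNA library
#'
#' @param genotype genotype label carried into the library.
#' @param n_pirna_pairs number of transposon piRNA events; each event emits
#'   one antisense initiator read and one sense read (a true 10-nt-overlap
#'   responder with probability `p_pingpong`, otherwise an unrelated sense
#'   read).
#' @param p_pingpong fraction of sense reads generated as exact
#'   10-nt-5'-overlap responders to an antisense initiator.
#' @param p_1U_antisense marginal probability that an antisense read starts
#'   with T (uridine in the RNA).
#' @param p_10A_sense marginal probability that a sense read carries A at
#'   position 10 (1-based).
#' @param pirna_length_dist named probability vector over piRNA lengths
#'   23..29.
#' @param n_mirna_reads total count of miRNA reads.
#' @param mirna_length_dist named probability vector over miRNA lengths
#'   21..23.
#' @param n_rrna_reads total count of rRNA fragments (discarded by the
#'   total-RPM normaliser downstream).
#' @param n_cluster_reads total count of cluster-derived uniquely mapping
#'   reads, split between the uni-strand and dual-strand cluster.  The
#'   dual-strand half scales with `reduction_factor`; the uni-strand half
#'   does not (uni-strand clusters are unaffected by loss of ping-pong).
#' @param reduction_factor positive multiplier on ping-pong-dependent piRNA
#'   counts (the genotype effect).
#' @param substitution_rate per-base substitution rate applied to emitted
#'   piRNA reads (default 0; exercise the edit-tolerant matcher).
#' @param positioning `"hotspot"` (default): reads start at a limited set of
#'   well-separated 5' sites per family, non-responder sense reads sit at a
#'   uniform non-10 offset from an initiator site so that the offset-10 mass
#'   of the combined histogram measures the planted responder fraction;
#'   `"uniform"`: all 5' positions uniform over the consensus.
#' @param sites_per_family number of 5' hotspot sites per family and strand.
#' @param seed integer seed for the single RNG stream of the library.
#' @return a list of class `library_params`.
#' @export
library_params <- function(genotype = "control",
                           n_pirna_pairs = 5000L,
                           p_pingpong = 0.5,
                           p_1U_antisense = 0.75,
                           p_10A_sense = 0.47,
                           pirna_length_dist = c(`23` = 0.05, `24` = 0.15,
                                                 `25` = 0.25, `26` = 0.25,
                                                 `27` = 0.15, `28` = 0.10,
                                                 `29` = 0.05),
                           n_mirna_reads = 5000L,
                           mirna_length_dist = c(`21` = 0.25, `22` = 0.50,
                                                 `23` = 0.25),
                           n_rrna_reads = 500L,
                           n_cluster_reads = 2000L,
                           reduction_factor = 1,
                           substitution_rate = 0,
                           positioning = c("hotspot", "uniform"),
                           sites_per_family = 8L,
                           seed = 1L) {
  stopifnot_prob(p_pingpong, "p_pingpong")
  stopifnot_prob(p_1U_antisense, "p_1U_antisense")
  stopifnot_prob(p_10A_sense, "p_10A_sense")
  stopifnot_prob(substitution_rate, "substitution_rate")
  check_length_dist(pirna_length_dist, "pirna_length_dist", 23:29)
  check_length_dist(mirna_length_dist, "mirna_length_dist", 21:23)
  if (n_pirna_pairs < 0 || n_mirna_reads < 0 || n_rrna_reads < 0 ||
      n_cluster_reads < 0)
    stop("read counts must be >= 0", call. = FALSE)
  if (!is.numeric(reduction_factor) || reduction_factor <= 0)
    stop("reduction_factor must be positive", call. = FALSE)
  structure(list(genotype = genotype,
                 n_pirna_pairs = as.integer(n_pirna_pairs),
                 p_pingpong = p_pingpong,
                 p_1U_antisense = p_1U_antisense,
                 p_10A_sense = p_10A_sense,
                 pirna_length_dist = pirna_length_dist,
                 n_mirna_reads = as.integer(n_mirna_reads),
                 mirna_length_dist = mirna_length_dist,
                 n_rrna_reads = as.integer(n_rrna_reads),
                 n_cluster_reads = as.integer(n_cluster_reads),
                 reduction_factor = reduction_factor,
                 substitution_rate = substitution_rate,
                 positioning = match.arg(positioning),
                 sites_per_family = as.integer(sites_per_family),
                 seed = as.integer(seed)),
            class = "library_params")
}

## solve the shared-base coupling (see header comment)
solve_bias_coupling <- function(pp, p1u, p10a) {
  if (pp == 0) return(list(q = 0, q_a = p1u, q_s = p10a))
  lo <- max(0, (p1u - (1 - pp)) / pp, (p10a - (1 - pp)) / pp)
  hi <- min(1, p1u / pp, p10a / pp)
  if (lo > hi + 1e-12)
    stop(sprintf(paste0("requested biases are geometrically infeasible: ",
                        "|p_1U_antisense - p_10A_sense| = %.3f exceeds ",
                        "1 - p_pingpong = %.3f (the pair overlap base is ",
                        "shared)"), abs(p1u - p10a), 1 - pp), call. = FALSE)
  q <- (lo + hi) / 2
  q_a <- if (pp < 1) min(1, max(0, (p1u - pp * q) / (1 - pp))) else 0
  q_s <- if (pp < 1) min(1, max(0, (p10a - pp * q) / (1 - pp))) else 0
  list(q = q, q_a = q_a, q_s = q_s)
}

sample_lengths <- function(dist, n) {
  as.integer(sample_int(names(dist), n, replace = TRUE, prob = dist))
}

mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  vapply(chars, function(ch) {
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample_int(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
}

## Pick, per family, well-separated (>= 70 nt) hotspot sites.  Pools are
## balanced on two consensus bases: the shared pair base at j (A <=>
## antisense 1U and responder 10A) and the responder first base at j - 9
## (T at a natural 1/4 rate in both pools), so that conditioning a bias
## statistic on the first base does not leak the 10A coin through site
## identity.  Sites are sampled over the whole usable consensus with a
## separation constraint, so the base requirements are almost always
## satisfiable.
pick_sites <- function(cons, k) {
  L <- nchar(cons)
  margin <- 30L
  usable <- L - 2L * margin
  ## each placed site removes < 140 candidate positions, so this cap
  ## guarantees the greedy placement below always succeeds
  k <- max(1L, min(k, usable %/% 140L))
  cand <- margin:(L - margin)
  bases_at <- function(pos) substring(cons, pos, pos)
  at_j <- bases_at(cand) == "A"
  at_f <- bases_at(cand - 9L) == "T"
  want_a <- rep_len(c(TRUE, FALSE), k)
  want_t <- logical(k)                    # responder first base T at 1/4,
  for (pool in c(TRUE, FALSE)) {          # balanced within each j-base pool
    idx <- which(want_a == pool)
    want_t[idx] <- rep_len(c(TRUE, FALSE, FALSE, FALSE), length(idx))
  }
  available <- rep(TRUE, length(cand))
  j <- integer(k)
  for (i in seq_len(k)) {
    hit <- cand[available & (at_j == want_a[i]) & (at_f == want_t[i])]
    if (!length(hit)) hit <- cand[available & (at_j == want_a[i])]
    if (!length(hit)) hit <- cand[available]
    if (!length(hit))
      stop("consensus too short to place separated hotspot sites",
           call. = FALSE)
    j[i] <- sample_int(hit, 1L)
    available[abs(cand - j[i]) < 70L] <- FALSE
  }
  sort(j)  # 1-based plus-strand coordinates of the antisense 5' sites
}

#' Simulate a small RNA library with planted ping-pong structure
#'
#' Emits transposon-derived sense/antisense piRNA pairs with a tunable exact
#' 10-nt 5'-overlap responder fraction, marginal 1U (antisense) and 10A
#' (sense) biases, miRNA reads from annotated miRNA genes, rRNA fragments,
#' and uniquely mapping cluster reads, together with a ground-truth record.
#' Reads are stored in the DNA alphabet (T, not U).  For a fixed seed the
#' output is bit-reproducible.
#'
#' @param panel a `te_panel` from [generate_te_panel()].
#' @param params a `library_params` object.
#' @return list with elements `library` (a `smallrna_library`) and `truth`
#'   (realized totals and bias fractions recomputed from the emitted reads,
#'   plus the planted responder record).
#' @export
simulate_library <- function(panel, params) {
  stopifnot(inherits(panel, "te_panel"), inherits(params, "library_params"))
  if (length(panel$families) == 0L) stop("panel has no families")

  with_seed(params$seed, {
    fams <- panel$families
    nf <- length(fams)
    fam_w <- exp(-0.35 * (seq_len(nf) - 1))
    fam_w <- fam_w / sum(fam_w)

    n_ev <- as.integer(round(params$n_pirna_pairs * params$reduction_factor))
    coup <- solve_bias_coupling(params$p_pingpong, params$p_1U_antisense,
                                params$p_10A_sense)

    anti_seq <- sense_seq <- character(0)
    anti_fam <- sense_fam <- character(0)
    responder <- logical(0)

    if (n_ev > 0L) {
      fam_i <- sample.int(nf, n_ev, replace = TRUE, prob = fam_w)
      responder <- runif(n_ev) < params$p_pingpong
      cA <- ifelse(responder, runif(n_ev) < coup$q, runif(n_ev) < coup$q_a)
      la <- sample_lengths(params$pirna_length_dist, n_ev)
      ls <- sample_lengths(params$pirna_length_dist, n_ev)
      J <- integer(n_ev)   # 1-based plus-strand coordinate of antisense 5'
      I <- integer(n_ev)   # 1-based plus-strand coordinate of sense 5'

      if (params$positioning == "hotspot") {
        ## hotspot sites are features of the reference, not of the library:
        ## they are drawn from a panel-derived seed so that every simulated
        ## genotype produces piRNAs from the same loci
        site_seed <- if (is.na(panel$seed)) 7L else panel$seed
        sites <- with_seed(site_seed,
                           lapply(fams, pick_sites,
                                  k = params$sites_per_family))
        ## per family and site: consensus base at j - o + 10 (a sense read's
        ## position 10) and at j - o + 1 (its first base), offsets o = 1..29
        off_base <- lapply(seq_len(nf), function(f) {
          js <- sites[[f]]
          m <- outer(js, 1:29, function(j, o) j - o + 10L)
          matrix(substring(fams[f], m, m), nrow = length(js))
        })
        off_first <- lapply(seq_len(nf), function(f) {
          js <- sites[[f]]
          m <- outer(js, 1:29, function(j, o) j - o + 1L)
          matrix(substring(fams[f], m, m), nrow = length(js))
        })
        for (f in seq_len(nf)) {
          ev <- which(fam_i == f)
          if (!length(ev)) next
          js <- sites[[f]]
          jbase <- substring(fams[f], js, js)
          poolA <- which(jbase == "A"); poolB <- which(jbase != "A")
          if (!length(poolA)) poolA <- seq_along(js)
          if (!length(poolB)) poolB <- seq_along(js)
          si <- ifelse(cA[ev],
                       sample_int(poolA, length(ev), replace = TRUE),
                       sample_int(poolB, length(ev), replace = TRUE))
          J[ev] <- js[si]
          ## sense placement
          resp <- responder[ev]
          I[ev[resp]] <- J[ev[resp]] - 9L
          free <- ev[!resp]
          if (length(free)) {
            ## A free sense read sits at a non-10 offset from any hotspot
            ## site.  The (site, offset) cell is drawn jointly from three
            ## independent coins: the site-class coin (rate = the pair coin
            ## q, so the responder:free mass ratio is homogeneous across
            ## site classes and the combined histogram stays calibrated),
            ## the 10A coin and a first-base coin -- keeping position-1 and
            ## position-10 identities independent in the sense population.
            want_cls <- runif(length(free)) < coup$q
            want_a <- runif(length(free)) < coup$q_s
            want_t <- runif(length(free)) < 0.25
            ob <- off_base[[f]][, -10, drop = FALSE]
            ofb <- off_first[[f]][, -10, drop = FALSE]
            offs <- setdiff(1:29, 10L)
            cell_site <- row(ob)
            cell_off <- matrix(offs[col(ob)], nrow = nrow(ob))
            site_is_a <- substring(fams[f], js, js) == "A"
            cls <- site_is_a[cell_site]
            key3 <- paste0(cls, ".", ob == "A", ".", ofb == "T")
            key2 <- paste0(cls, ".", ob == "A")
            cells3 <- split(seq_along(ob), key3)
            cells2 <- split(seq_along(ob), key2)
            cells1 <- split(seq_along(ob), ob == "A")
            pick_cell <- function(wc, wa, wt) {
              m <- cells3[[paste0(wc, ".", wa, ".", wt)]]
              if (is.null(m)) m <- cells2[[paste0(wc, ".", wa)]]
              if (is.null(m)) m <- cells1[[as.character(wa)]]
              if (is.null(m)) m <- seq_along(ob)
              sample_int(m, 1L)
            }
            for (u in seq_along(free)) {
              cell <- pick_cell(want_cls[u], want_a[u], want_t[u])
              o <- cell_off[cell]
              J_site <- js[cell_site[cell]]
              I[free[u]] <- J_site - o + 1L
            }
          }
        }
      } else {  # uniform 5' positions
        for (f in seq_len(nf)) {
          ev <- which(fam_i == f)
          if (!length(ev)) next
          L <- nchar(fams[f])
          cand <- 30:(L - 30L)
          cbase <- substring(fams[f], cand, cand)
          posA <- cand[cbase == "A"]; posB <- cand[cbase != "A"]
          if (!length(posA)) posA <- cand
          if (!length(posB)) posB <- cand
          J[ev] <- ifelse(cA[ev],
                          sample_int(posA, length(ev), replace = TRUE),
                          sample_int(posB, length(ev), replace = TRUE))
          resp <- responder[ev]
          I[ev[resp]] <- J[ev[resp]] - 9L
          free <- ev[!resp]
          if (length(free)) {
            ## 10A conditioning: sense position-10 base is consensus[i + 9]
            want_a <- runif(length(free)) < coup$q_s
            p10 <- cand + 9L
            p10b <- substring(fams[f], p10, p10)
            iA <- cand[p10b == "A"]; iB <- cand[p10b != "A"]
            if (!length(iA)) iA <- cand
            if (!length(iB)) iB <- cand
            I[free] <- ifelse(want_a,
                              sample_int(iA, length(free), replace = TRUE),
                              sample_int(iB, length(free), replace = TRUE))
          }
        }
      }
      anti_seq <- revcomp(substring(fams[fam_i], J - la + 1L, J))
      sense_seq <- substring(fams[fam_i], I, I + ls - 1L)
      anti_fam <- names(fams)[fam_i]
      sense_fam <- names(fams)[fam_i]
      if (params$substitution_rate > 0) {
        anti_seq <- mutate_seqs(anti_seq, params$substitution_rate)
        sense_seq <- mutate_seqs(sense_seq, params$substitution_rate)
      }
    }

    ann <- panel$annotation
    genome <- panel$genome
    draw_interval_reads <- function(iv, n, lengths, strand, hotspots = 0L) {
      if (n <= 0L || nrow(iv) == 0L) return(character(0))
      which_iv <- sample.int(nrow(iv), n, replace = TRUE)
      len <- lengths(n)
      out <- character(n)
      for (r in seq_len(nrow(iv))) {
        sel <- which(which_iv == r)
        if (!length(sel)) next
        lo <- iv$start[r] + 1L
        hi <- iv$end[r] - 29L
        starts <- if (hotspots > 0L) {
          ## locus-determined 5' sites, shared by every simulated genotype
          sites <- unique(as.integer(round(seq(lo, max(lo, hi),
                                               length.out = hotspots))))
          sample_int(sites, length(sel), replace = TRUE)
        } else if (hi <= lo) rep(lo, length(sel))
        else sample_int(lo:hi, length(sel), replace = TRUE)
        seqs <- substring(genome[iv$chrom[r]], starts, starts + len[sel] - 1L)
        if (strand == "-") seqs <- revcomp(seqs)
        out[sel] <- seqs
      }
      out
    }

    mirna_iv <- ann[ann$class == "miRNA", , drop = FALSE]
    mirna_seq <- draw_interval_reads(
      mirna_iv, params$n_mirna_reads,
      function(n) sample_lengths(params$mirna_length_dist, n), "+",
      hotspots = 1L)

    rrna_iv <- ann[ann$class == "rRNA", , drop = FALSE]
    rrna_seq <- draw_interval_reads(
      rrna_iv, params$n_rrna_reads,
      function(n) sample_int(19:29, n, replace = TRUE), "+")

    uni_iv <- ann[ann$class == "cluster_unistrand", , drop = FALSE]
    dual_iv <- ann[ann$class == "cluster_dualstrand", , drop = FALSE]
    n_uni <- as.integer(round(params$n_cluster_reads / 2))
    n_dual <- as.integer(round(params$n_cluster_reads / 2 *
                                 params$reduction_factor))
    plen <- function(n) sample_lengths(params$pirna_length_dist, n)
    uni_seq <- draw_interval_reads(uni_iv, n_uni, plen, "-", hotspots = 12L)
    nd1 <- n_dual %/% 2L
    dual_seq <- c(draw_interval_reads(dual_iv, nd1, plen, "+", hotspots = 12L),
                  draw_interval_reads(dual_iv, n_dual - nd1, plen, "-",
                                      hotspots = 12L))

    all_seq <- c(anti_seq, sense_seq, mirna_seq, rrna_seq, uni_seq, dual_seq)
    reads <- collapse_reads(all_seq, rep(1L, length(all_seq)))

    lib <- smallrna_library(reads, library_id = params$genotype,
                            genotype = params$genotype,
                            log = log_line("simulate", length(all_seq),
                                           nrow(reads)))

    first_base <- function(s) substring(s, 1L, 1L)
    tenth_base <- function(s) substring(s, 10L, 10L)
    sense_non1u <- sense_seq[first_base(sense_seq) != "T"]
    truth <- list(
      params = params,
      n_events = n_ev,
      n_responders = sum(responder),
      partnered_mass_fraction = if (n_ev > 0L) sum(responder) / n_ev else NA_real_,
      planted_pairs_by_family = if (n_ev > 0L)
        as.list(table(anti_fam[responder])) else list(),
      frac_1U_antisense = if (n_ev > 0L)
        mean(first_base(anti_seq) == "T") else NA_real_,
      frac_10A_sense = if (n_ev > 0L)
        mean(tenth_base(sense_seq) == "A") else NA_real_,
      frac_10A_sense_non1U = if (length(sense_non1u))
        mean(tenth_base(sense_non1u) == "A") else NA_real_,
      totals = c(te_pirna = 2L * n_ev, mirna = length(mirna_seq),
                 rrna = length(rrna_seq), cluster_uni = length(uni_seq),
                 cluster_dual = length(dual_seq),
                 all = length(all_seq)))

    list(library = lib, truth = truth)
  })
}

#' Write the ground-truth record of a simulated library as JSON
#'
#' @param truth the `truth` element returned by [simulate_library()].
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
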