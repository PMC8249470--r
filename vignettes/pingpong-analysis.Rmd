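---
title: "Quantifying the piRNA ping-pong signature in small RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the piRNA ping-pong signature in small RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

In *Drosophila* ovaries, PIWI-clade Argonautes silence transposons using
23–29-nt piRNA guides. The amplification loop that adapts this defense to
active transposons — the ping-pong cycle — leaves a precise statistical
fingerprint in sequencing data: pairs of sense and antisense piRNAs whose 5′
ends overlap by exactly 10 nt, an enrichment of U at position 1 of antisense
(Aub-bound) piRNAs, and an enrichment of A at position 10 of sense
(responder) piRNAs. `pingpongr` implements the quantification of these
signatures for collapsed small-RNA libraries, together with the surrounding
bookkeeping a genotype comparison needs: read classification against
annotation intervals, miRNA-normalized abundance per transposon family and
per genomic window, reduction filters, fold changes against a control
genotype, and — as a separate quantitative sub-module — exponential-recovery
fitting of FRAP traces for the nuage proteins that host the cycle.

Everything is exercised end-to-end on a synthetic data generator that
plants each signature with known parameters, so every stage of the pipeline
is testable without any sequencing download.

## The ping-pong statistic

Reads are matched to transposon consensus sequences on both strands with up
to two edits (substitutions and indels) and reduced to their 5′-end
coordinate. For a sense 5′ end at plus-strand coordinate $i$ and an
antisense 5′ end at $j$, the offset is the overlap length

$$o = j - i + 1,$$

so $o = 10$ is the canonical ping-pong configuration. For every *target*
alignment $t$, the partner histogram $H_t(o)$ adds the cloning/sequencing
count of each opposite-strand alignment in the same family at offset
$o \in \{1, \dots, 29\}$ and is normalized to 100%. The combined histogram
weights each partnered target by its own count:

$$H(o) = \sum_{t \in T} \frac{c_t}{\sum_{t' \in T} c_{t'}} \, H_t(o),
\qquad T = \{t : t \text{ has} \ge 1 \text{ valid partner}\},$$

and the *ping-pong fraction* is $H(10)$. Three declared conventions matter:

* **Offset convention.** "Distance" is overlap length (o = 10 at the
  signature), not the 5′–5′ gap. `pair_offset()` encodes it; a different
  convention would shift the histogram by one.
* **Partnerless targets.** A target with no opposite-strand partner within
  offsets 1–29 has an undefined (unnormalizable) histogram; it is excluded
  from the numerator *and* the weight denominator. This is the only reading
  under which every per-target histogram can be "normalized to 100%".
* **Every alignment is a candidate target**, on both strands, and every
  (read, placement) pair participates independently.

The implementation aggregates count mass by (family, strand, 5′ position);
a brute-force all-pairs enumeration over individual alignments is kept in
the test suite as an independent oracle and the two agree to 1e-9 on
hundreds of random libraries.

## Consensus matching

The matcher answers: at which 5′ coordinates does a read sit on a consensus
with at most `max_edits` Levenshtein edits? A placement is an
*anchored-start* alignment — the read's 5′-most base is aligned (match or
substitution) at the reported coordinate, gaps are internal, and the 3′ end
is free. This makes the 5′ coordinate well defined under indels, which is
what the downstream statistic consumes. Two consequences are handled
explicitly:

* An exact occurrence at $s$ induces *shadow* placements at $s \pm 1,
  s \pm 2$ with 1–2 edits (leading gap/substitution rearrangements of the
  same alignment). A placement is therefore suppressed when a strictly
  better one lies within `max_edits` positions on the same strand. Distinct
  occurrences separated further than that are all reported.
* Antisense placements are computed by scanning the reverse-complemented
  consensus and mapping coordinates by $x \mapsto L - 1 - x$, which makes
  the 5′ end of a minus-strand read the rightmost plus-strand base of its
  alignment by construction.

Family assignment follows a best-hit rule: a read contributes to every
family that holds a placement at its global minimum edit distance, fully in
each tied family (no fractional counts). Within those families, only
placements at the global minimum are kept by default (`stratum = "best"`);
`stratum = "all"` keeps every placement within the edit budget. The scan is
a banded dynamic program in C++ with early abandonment, plus iterative
deepening (almost all reads in practice resolve at the exact level).
Genome mapping, by contrast, is exact-only on both strands, with a
uniqueness flag and a multiplicity cap (default 100).

## Classification and normalization

A read is `miRNA` if any exact genomic placement overlaps an annotated
miRNA gene; else `rRNA` by the same rule; else `piRNA` if it is 23–29 nt
and overlaps a repeat interval; else `other`. The fixed priority prevents
double counting and is recorded in the report. Uniqueness is *not* required
for the repeat overlap by default (configurable), since the defining
annotation makes no uniqueness demand.

Two normalizers are provided: counts per million miRNA reads (the
cross-library normalizer used for all transposon and window abundances) and
counts per million non-rRNA library reads. Fold changes are
$\log_2((x + \varepsilon)/(x_{ctrl} + \varepsilon_{ctrl}))$ with a
pseudocount of 0.5 *reads* converted to each library's miRNA scale
($\varepsilon = 0.5 \cdot 10^6 / N_{miRNA}$); the pseudocount is symmetric,
so equal abundances give exactly 0 and double-zero families are damped to 0
rather than undefined.

Genomic windows tile each chromosome without overlap (5 kb genome-wide,
1 kb for cluster detail); a placement belongs to the single window holding
its 5′-end coordinate (alignment start on `+`, end − 1 on `-`), so
boundary-spanning reads are never double counted. The filter keeps windows
with control abundance ≥ 5 RPM (inclusive: "at least") and mutant reduction
strictly > 80% ("more than"); both thresholds are parameters.

## What the synthetic generator plants, and what it does not

`generate_te_panel()` builds a random reference: consensus sequences
embedded in a random genome (annotated as repeats), miRNA genes, an rRNA
locus, and one uni-strand plus one dual-strand piRNA cluster.
`simulate_library()` then emits, per piRNA event, one antisense initiator
and one sense read, the latter a true responder at exactly 10-nt 5′ overlap
with probability `p_pingpong`. Design points a user should know:

* **The shared overlap base.** In a 10-nt-overlap pair, the responder's
  position-10 base *is* the complement of the initiator's first base — one
  consensus base serves both. Requested marginals `p_1U_antisense` (over
  antisense reads) and `p_10A_sense` (over sense reads) therefore cannot
  both be free for paired reads; the generator solves for three
  subpopulation rates (paired pairs, unpaired initiators, free sense) such
  that both marginals hold exactly, which is feasible iff
  $|p_{1U} - p_{10A}| \le 1 - p_{pingpong}$. Infeasible requests error with
  this inequality rather than silently missing a marginal. This constraint
  is a real property of the geometry, not an implementation artifact.
* **Hotspot positioning (default).** Real piRNA 5′ ends pile up at a
  limited set of positions. Each family gets a set of well-separated
  (≥ 70 nt) 5′ sites, chosen once per *panel* (loci are features of the
  reference, shared by every genotype). Site pools are balanced on the pair
  base and on the responder first base, and free sense reads draw their
  (site, offset) jointly from coins for site class, position-10 base and
  first base — so the planted 10A bias is independent of the first-base
  identity and survives the non-1U restriction used by the headline
  statistic.
* **Calibration of H(10).** Free (non-responder) sense reads sit at a
  uniform offset in $\{1..29\}\setminus\{10\}$ from an initiator site. With
  isolated sites this makes the expected combined histogram value at offset
  10 equal to the planted responder mass fraction, so the statistic's
  parameter recovery can be tested sharply (observed agreement within
  ±0.002 at 10^4 reads; the acceptance tests allow ±0.03). A
  `positioning = "uniform"` mode scatters 5′ ends uniformly instead and is
  used to show the statistic produces no spurious offset-10 peak.
* **Genotype effect.** `reduction_factor` scales the number of piRNA events
  and the dual-strand cluster output; uni-strand cluster reads are not
  scaled, mirroring the biology in which uni-strand clusters do not depend
  on the ping-pong machinery.
* **Not modeled:** trimming/phasing kinetics, nuclear silencing, realistic
  genome composition or repeat degeneracy, sequencing quality. Reads are
  exact reference substrings unless `substitution_rate > 0`. Passing tests
  on this generator demonstrate the correctness and calibration of the
  *statistics*, not the biology of any real library.

The default four-genotype study configuration (`default_config()`) emulates
an *aub* loss-of-function allelic series with rescue transgenes:
piRNA:miRNA abundance ratios of 2.0 (heterozygous control), 0.38 (mutant),
2.0 (wild-type rescue) and 0.69 (methylation-deficient rescue) via
reduction factors 1 / 0.19 / 1 / 0.345, and sense non-1U 10A biases of
47 / 28 / 49 / 38%. The planted responder fractions (0.50 / 0.15 / 0.50 / 0.30) are free
parameters chosen to give the same qualitative ordering (control ≈ wt
rescue > md rescue > mutant); no printed value constrains them. Library
depth defaults to 20,000 piRNA events and 20,000 miRNA reads per genotype —
deep enough that binomial noise on the bias statistics is a few tenths of a
percentage point, while a full four-genotype pipeline run stays under half
a minute.

## FRAP quantification

Each trace carries per-frame mean intensities of the bleach zone (BL), a
background zone (BG) and a reference zone (REF). The correction is
$BL_{corr} = (BL - BG)/(REF - BG)$ (invariant under multiplicative
rescaling of all three channels), normalized to the mean of the five
pre-bleach frames, and the post-bleach series, re-zeroed at the first
post-bleach frame, is fitted to

$$y = a\,(1 - e^{-bt}) + c,$$

with the mobile fraction $a + c$. The fit is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`): $a, c \in [0, 2]$, $b > 0$, SSE tolerance 1e-10.
Initialization is data-driven ($c_0$ = first value, $a_0$ = net recovery
floored at 0.01, $b_0 = \ln 2 / t_{1/2}$ with $t_{1/2}$ floored at one
frame interval); whether the original analysis constrained its fitter is
unknown, so the bounds are a declared choice here. The default acquisition
layout is 5 pre-bleach + 115 post-bleach frames at 0.6144 s. On noiseless
model data the fit recovers parameters to machine precision; at Gaussian
noise σ = 0.02 the mobile-fraction estimator is unbiased to < 0.01 over
hundreds of simulations. The nuage:cytoplasm ratio is the separate
two-point statistic $N\!:\!C = (N - G)/(C - G)$.

## Numerical and edge-case decisions

* Empty subsets propagate `NA`, never 0: a family with no partnered target
  has an undefined histogram (`n_targets = 0`, all-`NA` values), an all-1U
  sense subset has an undefined 10A bias, an empty library is a warning.
* Zero normalizers (no miRNA reads, `REF = BG`, `C ≤ G`,
  non-positive pre-bleach mean) are errors naming the offending quantity or
  frame, not silent `Inf`s.
* Adapter trimming is exact-match, 3′-anchored, leftmost hit, minimum
  overlap 5; reads without an adapter hit are discarded by default because
  their insert boundary is unknown (`keep_untrimmed` retains them).
* All randomness flows through explicit integer seeds; a library, panel or
  pipeline run is byte-reproducible from its configuration.
* Bias statistics are count-weighted to match the histogram's weighting;
  `weight = "unique"` exposes the per-sequence alternative.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to make binomial error bars small relative to the
assertions: 500 random libraries (≤ 200 alignments) for the histogram
oracle, 60 libraries of 10^4 planted reads for parameter recovery (20 seeds
× responder fractions 0.2/0.5/0.8), 250 random matcher cases against a
naive per-start dynamic-programming oracle, 200 noisy FRAP simulations, and
the four-genotype default study above.

## Known limitations

* The exhaustive consensus scan is designed for panels of tens of
  families × kilobase consensus; it is not an indexed aligner for real
  genomes, and genome mapping is exact-only by design.
* Multi-mapping reads are fully counted in every tied family; there is no
  EM-style fractional assignment.
* The ping-pong statistic carries no significance model (no Z-score for
  the offset-10 peak); it is an estimator, and its sampling behavior is
  characterized only on the generator.
* Heterotypic vs homotypic ping-pong (which PIWI protein holds which read)
  requires IP-resolved libraries and is out of scope.
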