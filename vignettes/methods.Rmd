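---
title: "Methods: small RNA profiling, piRNA clusters and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling, piRNA clusters and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beehive)
```

# Scope and data model

beehive analyses small RNA sequencing libraries from insect
reproductive tissues after alignment: it consumes coordinate-addressed
alignments (SAM/BAM via Rsamtools, or a 7-column TSV) and a GFF3
annotation, and produces biotype profiles, piRNA clusters, biogenesis
signatures, tRNA-fragment classifications, transposon/gene targeting
tables and differential expression calls. Read mapping, adapter
trimming and novel-miRNA discovery are out of scope.

Internally all coordinates are 0-based half-open; GFF3 and SAM I/O
convert at the boundary, which keeps every overlap and distance
computation free of off-by-one adjustments. The 5′ end of a read is
`start` on the plus strand and `end − 1` on the minus strand. A
`ReadSet` row is one alignment; multi-mapped reads appear once per
reported alignment (each counted once by default — the upstream
mapper's multimap policy is not knowable from the alignment file
alone), and collapsing aggregates identical (sequence, locus) entries
into `copy_count` while conserving the total.

# Biotype assignment

Reads are labelled by a fixed precedence ladder, rRNA > tRNA >
pre-miRNA > other ncRNA > mRNA (exon ∪ intron) > unannotated, using
any-overlap on either strand. Structural RNAs outrank mRNA so tRNA
fragments are not mislabelled as mRNA degradation; strand is ignored
at this stage because a read antisense to a tRNA still indicates tRNA
origin ambiguity (strand-aware accounting lives in the targeting
module). Transposon overlap does not enter the ladder: the profile
categories mirror the standard library-composition view, and TE
accounting is a separate, strand-aware analysis. Assignment is
order-independent — permuting annotation records cannot change any
label, which the suite asserts.

# piRNA cluster identification

The caller follows the filter-then-cluster-then-post-filter recipe
used in insect germline studies:

1. **Putative piRNA filter.** Reads labelled rRNA/tRNA/pre-miRNA/other
   ncRNA are removed; protein-coding and unannotated reads stay. The
   26–31 nt window is *not* applied at the seeding stage (matching the
   stated order of operations) but is applied for signature analyses.
2. **Island calling.** On collapsed reads sorted by position, islands
   are maximal runs with consecutive start-to-start gaps ≤ `max_gap`
   (1000 bp). Islands qualify with ≥ `min_reads` (35) unique reads and
   ≥ `min_density` (10) collapsed reads/kb. The gap default mirrors
   the merge distance; the read floor mirrors the density-clustering
   minimum used by comparable callers. Both density conventions
   (collapsed by default) are arguments.
3. **Size fraction.** Clusters with < 50% of total (uncollapsed) reads
   at 26–31 nt are removed; exactly 50% survives, because the rule
   removes only "less than".
4. **Merge and minimum length.** Transitive merging of clusters
   overlapping or within 1 kb, then removal of clusters < 200 bp.
   Implemented as a single sorted sweep with a running envelope, which
   equals the transitive closure; the suite proves equality with a
   brute-force fixpoint merge and idempotence.
5. **Strandedness.** `plus`/`minus` only when that strand's collapsed
   count strictly exceeds 2× the other in every tissue where the
   cluster has ≥ 1 collapsed read; ties and exact doubles are
   bidirectional. In single-library mode the conjunction reduces to
   that library.

Cross-tissue overlap sets reuse the same 1 kb unification rule, since
no separate criterion is stated for it.

Island bounds are the min/max of member-read coordinates, so at
realistic background-read densities boundaries are resolved only to
about the `max_gap` scale: a stray intergenic read within 1 kb of a
cluster edge joins the island. The parameter-recovery suite therefore
asserts boundary accuracy (interval Jaccard ≥ 0.5 matching with recall
and precision ≥ 0.9) under sparse-rain conditions, while the
end-to-end demo asserts detection, one-truth-per-call and strand
identity at higher rain.

# Biogenesis signatures

1U/10A fractions are computed in read orientation, copy-weighted,
intended for the 26–31 nt window. The ping-pong histogram counts
opposite-strand pairs by 5′-end span o = q − p + 1 ∈ 1..30, weighted
by the product of copy counts (unique-pair mode available); the
phasing histogram counts 3′→5′ distances d ∈ 1..50 between
consecutive same-strand reads in transcription direction, so minus
strand logic mirrors plus.

Both Z-scores compare the signal bin (o = 10, d = 1) with the mean of
the remaining bins. The background scale is

`max(sd(background), sqrt(mean(background)))`

— the empirical sd floored at the Poisson value. The floor is the one
numerical choice that departs from the plain z-construction: histogram
bins are counts, and with ~29–49 background bins the empirical sd is
underestimated in roughly half of null draws, which produces
spuriously extreme scores on null data. A pure-Poisson study of the
statistic shows null coverage of |Z| < 2 at about 0.96 per replicate
with the floor (0.91–0.93 without); the criterion in the acceptance
suite asserts ≥ 0.95 over 100 seeded replicates. With an entirely
empty background the score has no scale and is flagged `NA`; a flat
histogram yields Z = 0. Z-scores are not computed below 50 reads.

Two null-design points matter when calibrating these scores on
simulated data. First, the generator's 1U planting selects read
positions conditioned on genome bases; on a short toy genome this
freezes sequence-specific dyad patterns into the overlap bins, so
calibration nulls sample positions uniformly (`cluster_u1 = NA`).
Second, the phasing null must place 5′ ends with mean spacing far
above the 50 nt window (the package uses ~500 bp); at high density the
spacing distribution decays geometrically *inside* the window and any
read set looks phased — a property of the statistic, not a bug, and
the reason phasing comparisons across libraries should hold read
depth per region roughly constant.

# tRNA fragment classification

Reads sense to a tRNA gene are converted to 1-based mature
coordinates, mirrored for minus-strand genes; reads running ≤ 2 nt
past the mature 3′ end are clipped to L (non-templated additions next
to the CCA tail), longer overhangs are dropped, antisense reads are
excluded and counted. The five positional classes use a 5′ tolerance
of 2 nt, a 3′ terminus zone L−2..L (accommodating CCA) and an
anticodon loop window of the anticodon start ± 3 (all arguments). The
rules are applied as an ordered decision list, which makes the classes
exclusive and total; the suite proves, by exhaustive enumeration of
all (s, e) pairs against an independently coded oracle, that the five
classes partition the space. Abundance tables key fragments by exact
(tRNA gene, s, e) and normalize within each sample's tRF total;
isodecoder views sum gene copies sharing an anticodon label.

# Feature targeting

Putative piRNAs (26–31 nt, ncRNA-filtered) are assigned to at most one
feature by category precedence TE > exon > intron (configurable; the
disjoint accounting matches per-category percentage tables), requiring
≥ 50% of the read length to overlap, with orientation recorded
relative to the feature strand. Intergenic reads are the total minus
assigned — an exact conservation the suite asserts. TE family tables
report percentages over TE-mapped reads of observed families; class
I/II proportions between tissues are compared with Pearson's
chi-squared without continuity correction, flagging expected cells
below 1. Differential antisense targeting delegates to the exact test
below on per-feature antisense counts.

# Differential expression

The test is a documented, self-contained conditioned exact test in the
Robinson–Smyth style; replicating any proprietary implementation's
numeric output is a non-goal.

* **Normalization.** factor_j = total_j / geometric mean of totals;
  normalized count = count / factor.
* **Dispersion.** Method of moments: the mean over features and
  replicated groups of (s² − m)/m² on normalized counts, floored at 0.
  Simulation recovery: Poisson data give estimates ≤ 0.05, data with
  φ = 0.2 give estimates in [0.1, 0.3] at 2000 features.
* **Exact test.** Group sums are scaled to effective equal sizes and
  rounded; conditional on the total t, the split follows the
  conditional law of two negative binomials with sizes n_A/φ and
  n_B/φ, which is free of the mean (the suite verifies this
  mean-invariance explicitly) and reduces to Binomial(t, n_A/(n_A+n_B))
  at φ = 0. The two-sided p-value sums conditional probabilities ≤ the
  observed one (with a 1e−8 relative tolerance on the equality, the
  usual guard against floating-point ties); t = 0 gives p = 1.
* **Calls.** BH-corrected FDR < 0.01, fold change > 5 on normalized
  tissue means, and tissue-mean raw count ≥ 5 ("≥ 5 counts in at least
  one tissue" is read as the tissue mean). Fold changes use pseudocount
  0; zero denominators fall into the "unique" category, defined as
  mean normalized count ≥ 5 in one tissue and raw zero in every sample
  of the other. Summaries count unique features within the
  up-regulated DE set, with "up-regulated but not unique" reported
  separately.

PCA plumbing uses log2(CPM+1), feature centering, and `prcomp`;
coordinates are deterministic up to component sign.

# The synthetic-data generator

`make_toy_genome()` plants non-overlapping features on a random
genome: genes with exons/introns, tRNA genes (length 75 nt including
CCA, anticodon at position 34), miRNA hairpins, rRNAs, other ncRNAs,
TE remnants from class I (R2, Gypsy, Copia) and class II (Mariner/TC1,
PiggyBac) families — a fraction nested inside designated piRNA cluster
intervals — and the cluster intervals themselves, separated by a 3 kb
buffer so recovered clusters are attributable to a single truth.

`simulate_tissue_library()` draws reads from a mixture over four
sources: miRNA reads (21–23 nt, sense within hairpins), tRF reads from
a fragment catalog on tRNA genes (32–33 nt classes dominate, GlyGCC
up-weighted), piRNA reads inside cluster intervals, and uniform
background rain (13–43 nt). Default tissue profiles are descriptive
labels for mixture presets — semen-like tRF-heavy (0.60), ovary- and
egg-like piRNA-heavy (0.70/0.65, lengths peaked at 29 nt),
testis-/spermatheca-like miRNA-heavy — chosen once as the package's
working defaults. Cluster reads carry a planted 1U bias (positions are
drawn from base-conditioned position classes so the realized fraction
is exactly binomial at the planted rate), a ping-pong fraction
(opposite-strand partners with 5′ ends offset by 9; because the
partner's 10th base is the complement of the primary's first, planted
1U automatically produces partner 10A), and a phased fraction
(head-to-tail trails at distance 1). Unidirectional clusters place 90%
of reads on the main strand — comfortably beyond the 2× strandedness
rule at tested depths while keeping the minor strand non-empty.
Alignments are exact by construction: the analysis operates
post-mapping, so no mismatch model is needed. Each library draws from
an RNG stream derived from (master seed, sample id), so adding a
sample never perturbs others, and fixed seeds give byte-identical
outputs.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: sequencing error and
modification-induced mismatches, multimapping ambiguity across
repetitive copies, non-uniform genomic background (real "rain"
concentrates in repeats), tRNA modifications that truncate reverse
transcription, and genome-scale cluster counts. The toy genome:library
ratio is chosen so that background rain density stays well below the
island caller's density criterion, as it does in real libraries; at
unrealistically small ratios the rain alone would satisfy the
criterion and no caller could behave sensibly.

`simulate_count_matrix()` drives the DE calibration: log-uniform base
means in [10, 200], NB draws at a common dispersion, multiplicative
planted effects.

# Problem sizes and determinism

The test suite runs at deliberately small scale — 500-read oracle
instances, 5000-read libraries on 0.15–1 Mb genomes, 2000-feature
count matrices, 100-replicate null calibrations — sizes at which every
brute-force oracle is exact and the whole suite completes in well
under a minute. The shipped demo configuration (1.5 Mb genome, two
tissues × two replicates × 5000 reads) runs end to end in a few
seconds and rewrites byte-identical stage outputs when re-run with the
same config; no stage caching is implemented because a content cache
adds failure modes without benefit at these scales.

# Known limitations

* One consensus cluster caller stands in for a multi-tool consensus;
  its parameters are exposed rather than tuned to any external tool.
* Boundary resolution of clusters is limited by `max_gap` (above).
* The common-dispersion exact test has no tag-wise shrinkage or GLM
  covariates; strongly feature-dependent dispersion will inflate its
  tails.
* Fractional multimapper weighting (`n_hits`) is carried through the
  data model but single-count assignment is the default everywhere.
* Biotype precedence resolves multi-overlap reads deterministically;
  libraries dominated by loci where annotations nest unusually (e.g.
  TE fragments inside exons) should revisit the targeting precedence
  argument.
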