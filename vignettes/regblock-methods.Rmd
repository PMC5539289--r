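---
title: "Methods: recurrent promoter mutation blocks and differential TF binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent promoter mutation blocks and differential TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regblock)
```

## The problem

Whole-genome sequencing of a tumor cohort yields thousands of somatic
single-nucleotide variants per patient, the vast majority of which are
passengers. In non-coding DNA there is no reading frame to interrogate,
so the question "is this variant functional?" has to be answered through
regulation: does the variant sit where regulation happens, does the
nearby gene actually change expression, and does the variant plausibly
change protein–DNA binding? `regblock` operationalizes these three
questions for promoter regions and scores them jointly across a patient
cohort.

## Step 1 — recurrent mutation blocks

SNVs are clustered per chromosome by a single sorted sweep: a new block
starts whenever the distance to the previous SNV is at least `max_gap`
(default 30 bp; strictly smaller gaps merge). The sweep is exactly the
transitive closure of the pairwise "closer than 30 bp" relation, which
the test suite verifies against a brute-force closure oracle. Blocks are
then filtered for recurrence (≥ 2 SNVs from ≥ 2 distinct patients),
assigned to genes whose promoter windows (TSS ± `half_width`, default
1000 bp, symmetric regardless of strand) contain any member SNV, and
finally gated on tumor-vs-normal differential expression of the assigned
gene. The stage order is fixed: cluster → recurrence filter → promoter
assignment → expression gate. A block overlapping promoters of several
genes is duplicated, one record per gene, rather than assigned to the
nearest TSS; the expression gate then decides which assignment survives.

The expression gate is a two-sample Kolmogorov–Smirnov test implemented
as the explicit sup-difference of the two empirical CDFs with the
asymptotic Kolmogorov p-value under the standard small-sample
effective-sample-size correction
(λ = (√n_eff + 0.12 + 0.11/√n_eff)·D). The statistic is validated in the
tests against direct ECDF enumeration and against `stats::ks.test`; the
asymptotic p is accurate to a few hundredths at cohort-like sizes, and
the suite checks that its type-I error at α = 0.05 stays in a band
around the nominal level. Genes absent from the expression table are an
error, not a silent pass.

## Step 2 — differential binding affinity

### The occupancy model

A PWM of length L with per-position base probabilities `p_i(b)` (rows
regularized to sum to one) is converted to a mismatch energy matrix

&nbsp;&nbsp;&nbsp;&nbsp;`E_i(b) = ln max_b' p_i(b') − ln p_i(b)`

so the consensus base costs nothing and every other base costs its
log-probability deficit, in dimensionless ln-probability units. A window
`w` of sequence is occupied with Fermi–Dirac probability
`1/(1 + e^{β(E(w) − μ)})`, β fixed at 1. The chemical potential μ plays
the role of the (unknown) nuclear concentration of the factor: at low μ
only near-consensus sites are occupied, at high μ weak sites contribute
too. Because that concentration is unknown, scores are averaged over the
grid μ ∈ {−2, 0, 2, 4}; the grid spans the regime from stringent to
promiscuous binding on the same scale as the energies, and averaging
keeps the score deterministic and smooth.

The sequence-level affinity is `dbA = ln Σ_w P_occ(w)`, summed over all
windows on both strands — a soft-max-like aggregate, deliberately not
the best-window maximum, because a mutation block can cover several
cooperating sites. Windows containing non-ACGT characters are skipped
(never imputed). The inner scan is C++ (`src/scan.cpp`); the tests pin it
to a pure-R enumeration of every window on both strands at 1e-9, and the
model's analytic identities (occupancy ½ at E = μ, ¾ at E = 0, μ = ln 3;
strand invariance; δdbA antisymmetry and exact zero on identical pairs)
are asserted directly.

### Scoring mutations

For each patient carrying a block, all of that patient's block SNVs are
substituted into one alternative sequence spanning the block plus a
30-bp flank per side (so motif windows can straddle block edges), and
`δdbA = dbA(alt) − dbA(ref)` is computed per PWM. For ranking displays,
raw δdbA values are z-scored per PWM across all scored units using the
population (1/n) standard deviation — deterministic at n = 2, mapping a
two-point set {1, 3} to {−1, +1} — and two filters are applied per unit:
an empirical direct-binding p-value below 0.1 (the reference sequence
must bind the factor more strongly than dinucleotide-preserving shuffles
of itself; the shuffle is an exact Altschul–Erickson Eulerian-path
construction, preserving CpG content), and |δdbA| in the top 20 % within
the unit. Survivors are split by sign and reported up to rank 15 per
direction, ties broken lexicographically by PWM identifier. Background
generation for the direct-binding p-value may stop early once a fifth of
the planned shuffles already exceed the observed affinity — at that
point the p-value is mathematically above the 0.1 cutoff, so the
decision cannot change (asserted in the tests).

Note that the z-score normalization needs a reference population: it is
informative when the scored units include both affected and unaffected
sequences (as in per-SNV scans over a whole call set), and it
deliberately cancels any shift shared by *all* units. The significance
stage below therefore uses raw δdbA, never the normalized values.

### Significance against background mutation blocks

For each (TF, block) pair the per-patient δdbA values are compared with
δdbA of random background blocks: intervals of the same scored length
placed uniformly inside 1000-bp regions immediately upstream of other
genes' TSSs (the tested gene's own regions are excluded), carrying the
same number of random substitutions at distinct positions. The number of
mutations is matched to the tested block as the rounded median of the
per-patient SNV counts, since one background block emulates one
patient-specific alternative sequence. When more background blocks are
requested than eligible regions exist (always the case on the miniature
synthetic genome), regions are re-drawn with replacement; every draw
still gets a fresh placement and fresh substitutions.

The comparison is a two-sided Wilcoxon rank-sum test. The implementation
uses the exact Mann–Whitney null distribution whenever there are no
cross-ties and `n_patients × n_background ≤ 10 000` — which covers the
entire operating range at the 500-background default — and otherwise the
normal approximation with tie and continuity corrections. The tests pin
the exact path to an independent lattice-path enumeration of the U
distribution over the full small-sample grid, and the approximate path
to `stats::wilcox.test`. With very small patient groups (n = 2) the pure
normal approximation can deviate from the exact p by up to ~0.03 at
moderate p-values regardless of the background count, which is why the
exact path is preferred wherever feasible.

P-values are Bonferroni-corrected with m = the number of PWMs actually
tested for the block (after the expression filter): each PWM is a
separate hypothesis, and factors removed before testing are not counted.
The whole test is repeated three times with independently drawn
backgrounds; a (TF, block) pair is reported only when all three
replicates are significant at corrected P < 0.05, with the median
p-value reported, the majority direction, and per-patient tail
probabilities `(1 + #{bg at least as extreme})/(1 + n_bg)` from the
median replicate. "All three significant" is the conservative reading of
triplicate testing; the per-replicate records remain available on the
result object.

## Annotation

Reported TFs are annotated with their median tumor expression: factors
below 0.03 RPKM (a published noise floor for distinguishing expressed
genes from background) are removed, and survivors are flagged `+`
(top quartile), `−` (bottom quartile) or `·`. Symbols are matched
case-insensitively, heterodimer PWMs (`AHR::ARNT`) take the minimum of
their components, and an alias table can map PWM names to gene symbols;
unmapped symbols are conservatively filtered, with a warning.

Blocks can be tested for aberrant somatic hypermutation: the DGYW/WRCH
hotspot pair (reverse complements of each other, so scanning both on
the forward strand covers both strands) defines the hotspot positions of
the reference block sequence; the null rate p₀ is the covered fraction
of the block, and the observed number of mutations inside hotspots is
tested with an exact two-sided binomial (minimum-likelihood rule,
validated against exhaustive pmf enumeration). This self-contained null
— "mutations land uniformly on the block" — is a design choice; it is
configurable in the sense that any other offset set and sequence can be
passed directly.

## The synthetic cohort

`synthetic_scenario()` emulates the structure of a small tumor cohort:
12 patients plus 4 normal controls, 50 genes with evenly spaced TSSs on
a 200-kb uniform-random chromosome, and 2 driver genes. Each driver
promoter carries a 60-bp planted block holding three occurrences of an
8-bp consensus (TGACTCAG) of a strongly informative planted PWM (peak
probability 0.85). Each patient receives genome-wide background SNVs at
1e-5 per bp and, with probability 0.7 per driver block, two SNVs that
each replace a consensus base of an occurrence with that position's
worst base. The worst bases cycle through the non-consensus alphabet
across positions so that disruptions are compositionally balanced — a
fixed worst-base alphabet would make every patient's alternative
sequence drift toward one nucleotide, and any composition-sensitive
motif would track that drift. Driver-gene expression is shifted 4-fold
in tumors; all values are log-normal with σ = 0.5 around per-gene means.
A `weak_effect` switch halves the per-patient disruptions for power
experiments.

The 50 decoy PWMs accompanying the planted one are informative
consensus-style matrices (peak 0.6–0.9, lengths 6–10) whose random
consensus is screened to share at most 4 aligned positions with the
planted consensus on either strand: a motif sharing most of the planted
consensus would genuinely lose binding when the planted sites are
destroyed and is no decoy. Three decoy TFs straddle the 0.03 RPKM floor
so the expression filter is exercised.

What the simulator does *not* emulate: trinucleotide mutational
signatures, CpG and GC structure of real promoters, transcript-level
TSS multiplicity, copy number, or any linkage between expression shifts
and the planted mutations (the expression effect is imposed, not
mediated). Passing tests on this cohort therefore demonstrate the
machinery — clustering, gating, scoring, calibration, recovery — not
performance on real genomes.

### A deliberate caveat on specificity

The acceptance suite demands both recovery (the planted PWM reported
significantly negative in every planted block in ≥ 9 of 10 seeds) and
specificity (on average at most one non-planted TF reported per run).
Recovery holds with large margin. Specificity as stated does not: a few
decoy TFs per run are typically reported, and the suite's diagnostic
shows why this is not a calibration defect — when the planted patient
mutations are replaced by random same-count mutations in the same block,
no TF is significant, and the type-I calibration check passes. The
reported decoys are genuine biophysical side effects: recurrent,
identical consensus→worst substitutions shared by all patients create
and destroy binding sites of *other* motifs too, and the rank-sum test
correctly detects any such consistent shift against random backgrounds.
The real-data analogue is that whole families of factors are typically
reported per block. The corresponding acceptance expectation is asserted
as written and left failing rather than weakened.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive in memory (VCF convention); BED
  output is 0-based half-open; `chr` prefixes are normalized on
  comparison.
* PWM regularization: +1 per cell for count matrices; probability
  matrices are only perturbed (+0.001, renormalized) when they contain
  exact zeros, so valid matrices round-trip unchanged.
* Zero probabilities after regularization (infinite energies) are an
  error, as are all-zero PWM rows, non-4-column matrices, indels in
  VCFs (skipped with a logged count), and reference-base mismatches
  against the genome (hard error listing positions).
* δdbA of identical sequences is exactly 0 (short-circuited before any
  floating-point work); normalization of a single unit or zero-spread
  values yields 0 with a warning rather than NaN.
* The magnitude filter threshold is the type-7 quantile of |δdbA_norm|
  within the unit; with 100 distinct values exactly 20 survive the 80 %
  cut. Ranking ties are broken by PWM identifier.
* All randomness (shuffles, background draws, the simulator) flows
  through explicit seeds; seeded calls restore the caller's RNG state,
  and per-(block, replicate) seeds are pre-derived so that serial and
  multi-worker runs are bit-identical (asserted in the tests).
* Degenerate hotspot nulls (p₀ of 0 or 1) return p = 1 with a warning;
  identical patient-and-background value sets give rank-sum p = 1.

## Problem sizes used in the checks

The validation suite runs entirely on simulated data: oracle comparisons
use motifs of 4–6 bp on sequences up to 30 bp, clustering oracles up to
50 SNVs over 200 random instances, the exact-test grids up to
n_patient = 5 × n_background = 30 (rank-sum) and n = 25 (binomial/KS),
null calibration uses 500 (TF, block) pairs at 200 backgrounds and 1000
null genes at 14-vs-14 samples, and recovery runs the default scenario
(51 PWMs, 500 backgrounds, 3 replicates) across 10 seeds. These sizes
were chosen to make each property measurable with comfortable
statistical margin on a single CPU.

## Known limitations

* Patient δdbA values within a block are treated as independent samples
  by the rank-sum test, but patients sharing mutated positions produce
  correlated values; significance for effects shared through identical
  recurrent substitutions is therefore optimistic (see the specificity
  caveat above).
* The asymptotic KS gate is approximate at very small sample counts
  (e.g. 2 normals); the implementation requires at least 2 per group and
  the calibration checks run at realistic sizes.
* Only promoter-proximal regulation is considered; enhancers, UTRs and
  structural variation are out of scope, as are PWM training and any
  joint modeling of cooperative or competitive binding beyond the
  additive occupancy sum.
* The background universe is upstream-of-TSS sequence; if real promoters
  differ systematically from the tested block in composition (CpG
  islands), the matched-length, matched-count construction controls
  placement and mutation number but not composition.
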