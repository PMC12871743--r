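---
title: "Screening for programmed dsRNA formation across meiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for programmed dsRNA formation across meiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiodsrna)
library(dplyr)
options(meiodsrna.verbose = FALSE)
```

## The problem

During synchronized budding-yeast meiosis, many transcripts form
double-stranded RNA (dsRNA) by base-pairing with natural antisense
transcripts (NATs) transcribed from the opposite strand of the same locus.
`meiodsrna` implements the computational side of that screen as a reusable,
tested pipeline over four kinds of evidence:

1. **Structural dynamics** — per-nucleotide DMS reactivity profiles across
   an ordered series of stages (vegetative `V`, pre-meiotic `P`, pachytene
   `T0`, then `T1`–`T6`). Intermolecular duplex formation protects bases and
   suppresses reactivity *one way*; ordinary intramolecular refolding moves
   reactivities in both directions.
2. **Antisense transcription** — strand-specific read counts per locus,
   summarized as the antisense read ratio through the time course.
3. **Cis-regulation** — URS1 (Ume6p) and MSE (Ndt80p) elements in the 1-kb
   region past each gene's 3' end, and strand-specific transcription
   initiation mapped from read 5' ends.
4. **Expression consequences** — pulsed sense-mRNA trajectories and
   sequentially convergent promoter architectures.

Because the deposited datasets are not required here, a synthetic-data
module generates every input with known ground truth; the test suite and
the acceptance script measure how faithfully the pipeline recovers what was
planted.

## Structural statistics

For one transcript, let $x_s(i)$ be the reactivity of position $i$ at stage
$s$ (with a missing mask). For every stage pair $(s, t)$ the package
computes:

* the Pearson correlation $r_{st}$ over positions covered in **both**
  stages (restricted to A/C positions when base identities are present,
  since DMS methylates adenine and cytosine). The minimum off-diagonal
  $r$ locates the largest structural change.
* the per-nucleotide difference $\Delta_{st}(i) = x_s(i) - x_t(i)$ for
  $s$ earlier than $t$, so positive values mean reactivity loss over time,
  and its median $\tilde\Delta_{st}$. A balanced rearrangement leaves the
  median near zero; one-way suppression drives it positive.

A stage pair enters only with at least `min_common` co-covered positions
(default 50 — correlations over transcript-scale vectors are unstable below
a few dozen points; the choice is configurable). An undefined correlation
(too little overlap, or a constant vector) is excluded rather than imputed:
missing is not dissimilar.

The screen applies the published cutoffs with strict inequalities exactly as
printed: genes with minimum $r$ *below* 0.6 (and 0.5), and dsRNA candidates
with maximal $\tilde\Delta$ *exceeding* 0.15. The class rule — stable when
minimum $r \ge 0.8$, otherwise unidirectional when the maximal median
difference exceeds the cutoff, otherwise bidirectional — operationalizes a
verbal taxonomy and is deliberately configurable; the screen itself depends
only on the two statistics.

Both A/C-restricted and all-nucleotide modes are provided
(`run_config(ac_only = )`); with bases absent or uninformative all covered
positions are used.

## Antisense read-ratio dynamics

Counts are TPM-normalized with sense and antisense entries of a locus as
separate terms in one per-stage sum (they share the locus length, since the
NATs span the sense locus), so each stage's TPM adds to $10^6$. The
antisense ratio is
$\mathrm{antisense\ TPM} / (\mathrm{sense} + \mathrm{antisense})$, with a
stage treated as missing when the locus total TPM is at or below 10 — the
floor is applied to the locus total because the published rule does not say
which quantity it floors; sense-only flooring is available. Because the two
strands share a length, this equals the read-count ratio up to library
composition.

Dynamic genes change their ratio by strictly more than 0.20 (absolute, in
ratio units — the trajectories are plotted as percentages, so "20%" reads
naturally as percentage points) with at most one missing stage. The
activation stage is the consecutive defined-stage interval with the largest
ratio increase, ties broken toward the earliest interval for determinism. A
gene is meiosis-specific when its defined V/P ratios stay at the ~15%
second-strand artifact background (within a 0.05 margin) and the called
interval starts at P or later; this is an explicit interpretation of a
verbal rule. Optional background subtraction
$(\rho - b)/(1 - b)$ is available but off by default.

Trajectory clustering uses centroid linkage on the centered Pearson
correlation distance $1 - r$, with the centroid recomputed as the mean
member profile over co-defined stages — the semantics of the Cluster 3.0
program, which `stats::hclust` cannot reproduce (its centroid method
requires squared Euclidean input). Centroid linkage on a correlation
distance can produce non-monotone merge heights; they are reported as
computed, and cuts are taken by merge order, which stays well defined.
Cluster pairs whose centroids share fewer than two defined stages get the
maximal distance 2; zero-variance rows are dropped with a warning.

## Motif scanning and TSS linkage

The URS1 (`TCGGCGGCTA`) and MSE (`GNCRCAAAW`) consensus strings become
position weight matrices by giving each disallowed base a small probability
`eps` (default 0.01) and splitting the remainder equally over allowed bases;
JASPAR text PFMs are also accepted (pseudocount 1). Windows are scored as
$\sum_w \log_2 (p_w(\mathrm{base}) / 0.25)$ against a uniform background —
appropriate for the uniform synthetic genomes and configurable for real
ones. `N` contributes 0 bits (neutral, never $-\infty$). A hit must reach
`min_score_fraction` (default 0.85) of the maximal attainable score; for
these short, partly degenerate motifs any single disallowed base costs
$\log_2(0.97/0.01) \approx 6.6$ bits, far more than the 15% slack, so in
practice the threshold admits exactly the IUPAC-consistent matches while
remaining meaningful for softer matrices. The published scans do not state
their threshold or background; score-fraction thresholding is our
interpretation.

Candidate antisense promoters are the 1-kb regions past each gene's 3' end,
extracted strand-aware and truncated (with a flag) at chromosome edges.
Enrichment of a motif in the regions of antisense-active genes against all
other genes' regions is a one-sided hypergeometric tail on the 2×2
region-count table, with a Haldane correction (0.5 per cell) for the odds
ratio when a cell is empty.

Read 5' ends (BED6; `chromStart` on `+`, `chromEnd - 1` on `-`) are merged
into initiation clusters when same-strand positions lie within
`merge_window` (default 20 nt, about four jitter standard deviations of the
nanopore 5'-end spread the generator emulates) and kept at
`min_count` ≥ 5 reads, which suppresses scattered degradation artifacts.
The representative position is the mode, ties broken toward the 5'-most
position in the transcription direction.

A motif is linked to a TSS cluster on the strand opposite the gene when the
TSS lies within 100 bp *downstream of the motif's downstream edge* in the
NAT transcription direction: for a `+` gene, offset = motif start − TSS; for
a `-` gene, offset = TSS − motif end + 1. Whether the published "within
100 bp" was measured from the motif start or end is unstated; the downstream
edge is the biologically natural origin (the element sits upstream of the
initiation site it drives) and the choice is configurable.

## Pulse detection and convergent promoters

Sense trajectories are z-scored per gene with the population standard
deviation (divisor $n$), making the pulse rule invariant to affine
transforms of the raw track. Within the window P–T1 (the published pulse
window; stages T1–T3 are only minutes apart), the peak is the maximal z
value; the rise is peak minus the minimum over stages up to the peak, the
fall is peak minus the minimum from after the peak through one stage past
the window's end, and the gene is pulsed when both reach `delta` (default
1.0 z-units). The rule is monotone in `delta` — raising it never admits a
gene — and is our operationalization of "a rapid increase followed by an
equally rapid decrease"; the alternative route, clustering z-scored
trajectories and labeling pulse-shaped clusters, is available through
`hierarchical_cluster()` on the z matrix, and the archetype-recovery test
shows the two routes agree on clean shapes.

Sense decline and antisense activation are *concurrent* when the maximal
TPM-decrease interval and the activation interval are identical or
adjacent, matching the time-course resolution. A locus is annotated as
carrying sequentially convergent promoters when URS1 is found in its 1-kb
upstream (sense-promoter) region **and** an MSE in its 1-kb downstream
(antisense-promoter) region; occupancy data are out of scope, so
convergence here is a motif-level call.

## The synthetic-data generator

The generator's defaults encode the study conditions: 9 stages; reactivity
suppression confined to a T1–T4 window at strength $f = 0.6$ with Gaussian
noise (sd 0.05, truncated at 0) and 10% missing coverage; ~15% background
antisense ratio rising to 0.45 on activation; 78% of activation intervals
concentrated in P→T0 and T0→T1 (0.39 each, the remainder uniform over later
intervals, none at V→P); gene loci with elements planted in 1-kb downstream
regions and antisense TSSs at geometric offsets (mean 40 nt, truncated at
100 nt, the published linkage window). Class labels are assigned by exact
quota rather than Bernoulli draws so recovery tests have fixed
denominators. With a fixed seed every output — including written files — is
byte-identical across runs.

Choices worth knowing about:

* **Baselines.** Per-transcript baselines are gamma-distributed
  (right-skewed, like normalized reactivities) and rescaled so the median is
  exactly 0.5; with zero noise the planted suppression then forces a median
  difference of exactly $0.5 \times f = 0.30$, which the exactness test
  asserts. The intramolecular class shifts equal halves of positions by
  $\pm\delta$ (down-shifts drawn from positions that can absorb them without
  truncation), so its median difference is exactly 0 under full coverage.
* **Counts.** Each (gene, stage) draws a shared gamma factor (mean 1,
  variance = dispersion) that scales both strand means before Poisson
  sampling. Marginally each strand count is negative-binomial with the
  stated mean and dispersion — the moment test checks this — while the
  antisense fraction behaves like a binomial split of locus output, since
  biological over-dispersion affects the whole locus, not each strand
  independently. Two independent NB strand draws at dispersion 0.3 would
  give the ratio a standard deviation near 0.2 and no estimator could
  locate activation intervals reliably.
* **Depth.** Per-gene depth is lognormal with median 500 reads/gene/stage
  (sdlog 0.8), the scale a typical yeast bulk RNA-seq run delivers. The
  binomial variance of the strand split, $p(1-p)/n$, ties the screen's
  error rates directly to this depth: at a few hundred reads the ratio's
  per-stage standard deviation is ~0.02–0.05, comfortably below the 0.20
  dynamic-gene threshold and the 0.30 activation step.
* **Sense trajectories.** Activated genes clear their sense mRNA across the
  activation interval (×0.25 from the interval's end stage onward), which is
  what makes decline and activation concurrent by construction; other genes
  are constant, pulsed (peak P or T0, ×6), rising or declining. The
  early-high antisense class (high V/P ratio decaying to background)
  reproduces the known pattern of antisense-first loci and gives the
  meiosis-specific classifier genuine negatives: with the default quotas
  roughly three quarters of dynamic genes are meiosis-specific, as in the
  real cohort.
* **Genomes.** Backgrounds are uniform and then scrubbed of every IUPAC
  occurrence of URS1/MSE on either strand outside the planted sites
  (junction artifacts from planting are redrawn too). This makes "exactly
  the planted coordinates recovered" a property of the construction rather
  than of a lucky seed — a 400-kb uniform genome would otherwise contain
  dozens of chance MSE matches.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the methods assume,
not real data. Reactivity noise is i.i.d. Gaussian and missingness is
i.i.d., whereas real coverage is bursty and sequence-dependent; suppression
is uniform across the transcript, whereas real duplexes protect segments;
genomes are uniform and motif-free outside planted sites, so scan
specificity against genomic background repeats is not measured; library
composition shifts across stages are mild. Recovery results therefore
demonstrate correctness of the estimators under the stated model, not
performance guarantees on real libraries.

Known limitations worth stating plainly:

* The median-difference statistic is robust to outliers but sensitive to
  the *shape* of the change distribution: if changes are bimodal at
  $\pm\delta$ with little mass near zero (the synthetic intramolecular
  model taken literally), a small coverage imbalance flips the median to
  $\pm\delta$. Real intramolecular remodeling is heterogeneous enough that
  this is a corner case, but candidate lists should be inspected, as the
  original screen did.
* Locating a single gene's maximal-decline interval degrades under heavy
  biological over-dispersion (the per-stage TPM coefficient of variation
  approaches the decline signal); the concurrency example runs at low
  dispersion where trajectories are smooth, as synchronized time courses
  are.
* TSS cluster representatives are modal positions; with few reads and wide
  jitter the mode can sit a few nt from the true start, which matters only
  when an offset is near the 100-bp linkage bound.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at: 500
transcripts × 9 stages × 200 nt (structural screen), 1,000 genes × 9 stages
(antisense dynamics), 100 gene loci on a ~0.4-Mb genome (motif/TSS), 400
z-score trajectories (pulses), plus ~500 randomized small instances checked
against brute-force oracles. A full run completes in well under a minute
per module on one CPU; all sizes are configurable upward through
`sim_config()`.
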