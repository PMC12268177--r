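---
title: "Methods: chromatin accessibility and expression dynamics in differentiating cortical neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin accessibility and expression dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsdyn)
```

## Scope and model of the data

`dhsdyn` reimplements, as a tested pipeline, the computational arm of a
DNase-seq / RNA-seq study of the four-day differentiation of deep-layer
excitatory cortical neurons: neural precursor cells sampled at embryonic
day 12 and their labelled progeny at E13, E14 and E16, two biological
replicates per stage. The pipeline starts downstream of read alignment:
its inputs are per-stage, per-replicate DNase I cut-site positions, gene
models, H3K4me3/H3K27me3 ChIP cut-site tracks, an enhancer–gene link
table, and a gene-by-sample count matrix with gene lengths.

Because no sequencing data ship with the package, a synthetic-data
generator with a planted ground truth stands in for the experiment. It is
first-class, tested code: every downstream stage is validated by whether
it recovers what the generator planted.

## The synthetic study

`sim_config()` fixes the study conditions. The defaults are the conditions
under which the pipeline is validated:

* **Genome and genes.** Two chromosomes of 5 Mb (10 Mb total), 1000 genes
  of 1.5–4 kb laid out in non-overlapping slots with enough clearance that
  promoter (1 kb up / 0.5 kb down of the TSS) and downstream (1 kb)
  windows of neighbouring genes never collide. This isolates the feature
  partition from layout artefacts; real genomes violate it, which is why
  the partition resolves overlaps by priority (below).
* **Accessibility truth.** Each gene draws a dynamic class —
  `always_open` (0.40), `never_open` (0.20), `opening_at_{E13,E14,E16}`
  (0.05/0.05/0.10) or `closing_at_{E13,E14,E16}` (0.05/0.05/0.10) — by
  exact quota, so planted counts are deterministic and testable. Opening
  at stage *s* means the promoter is inaccessible before *s* and
  accessible from *s* onwards.
* **Cut-site model.** DNase cuts follow an inhomogeneous Poisson process:
  0.01 cuts/bp background, 8-fold enriched inside accessible promoter
  windows and open enhancers. At these rates an accessible promoter
  expects ~120 cuts per replicate, chosen for desk-scale power: strong
  enough that a correct caller recovers essentially every planted window,
  weak enough that an uncalibrated null fails visibly. ChIP tracks use
  the same machinery with enriched windows of ±750 bp around the TSS of
  genes planted as carrying the mark; bivalent genes carry both marks.
* **Counts.** Negative binomial with dispersion 0.05, mean = trajectory
  mean × gene length (kb) × library depth (millions). Trajectory shapes
  are `flat`, `up` (doubling per sampled stage), `down`, and `transient`;
  a lognormal per-gene baseline (sdlog 0.5) spreads expression levels.
  Library sizes are 2e6 fragments with per-replicate depth factors
  (1, 1.25) so normalisation is actually exercised.
* **Coupling.** With probability 0.7, opening genes preferentially
  receive `up` trajectories, bivalent flags concentrate on opening genes,
  and Dmrt-repressor binding concentrates on bivalent genes. This plants
  the associations the overlap statistics are meant to detect (opening ∩
  upregulated, bivalent ∩ opening, Dmrt ∩ bivalent) without changing any
  marginal quota.
* **Seeds.** All randomness flows from one master seed through
  `child_seed()`, a purpose-keyed integer hash, so any track can be
  regenerated in isolation and the whole bundle is byte-reproducible.

What the generator does **not** emulate: sequence content, fragment-size
structure, mappability, copy-number and GC biases, enhancer-promoter
interaction noise, or overlapping gene models. Passing tests therefore
demonstrate correctness of the statistical machinery on data satisfying
its assumptions, not robustness to every artefact of real libraries.

## Peak calling

`kde_profile()` smooths cut sites with a Gaussian kernel (unit mass per
cut, tails truncated at five bandwidths). Evaluation on the grid is exact
— identical to direct summation at every grid point — which is enforced by
a brute-force oracle test at 1e-9 relative tolerance. Defaults: bandwidth
100 bp for DNase (promoter-scale smoothing, the order of magnitude
F-Seq-style callers use for DNase), 200 bp for ChIP marks, grid step
10 bp.

Under a uniform background of *n* cuts on *L* bp the KDE height at a point
has mean μ = *n/L* and variance σ² = *n/(L·2b√π)*. `background_threshold()`
offers the plain Gaussian quantile μ + z(1−p)·σ, but the height is a sum
of only ~10 kernel contributions at the default rates, so its null is
right-skewed (skewness ≈ 0.6) and the plain quantile is anti-conservative
by roughly two orders of magnitude at p = 1e-6. The caller therefore
defaults to a third-cumulant Cornish–Fisher correction,
z′ = z + (γ/6)(z² − 1) with γ = κ₃/σ³ and κ₃ = *n/(L·2π√3·b²)*, which
restores the nominal far-tail rate: 20 seeded uniform tracks of 1e5 cuts
on 10 Mb yield zero peaks in every run, while planted 8-fold windows are
still recovered with precision and recall 1.0. Both methods are exposed;
the uncorrected quantile remains available for comparison.

Candidate peaks are maximal above-threshold grid runs; runs closer than
50 bp merge, merged runs shorter than 50 bp are dropped, and chromosomes
with fewer than 10 cuts return no peaks (the degenerate null at *n* → 0
would otherwise call any positive density). A DHS is a cross-replicate
overlap (≥ 1 bp) of peaks, reported as the union span by default —
conservative inclusion for downstream overlap tests; intersection spans
are an option. Exclusion regions (blacklist emulation, sex chromosomes)
remove cuts before calling and shrink the effective length of the null.

## Feature partition and annotation

Every base is labelled once by the priority promoter > exon > intron >
downstream > distal: promoters are 1 kb upstream / 0.5 kb downstream of
the TSS (strand-aware; the minus-strand window is the endpoint mirror of
the plus-strand window through the TSS), exons and introns exclude
promoter bases, downstream is the 1 kb past the transcription end minus
higher-priority features, and the remainder is distal. A DHS is annotated
with the highest-priority label it overlaps (≥ 1 bp); base-pair-majority
assignment is available as an option. Enhancer–gene links are counted per
(DHS, enhancer) pair, matching per-enhancer link tables.

## Chromatin-state dynamics

A gene is DHS-positive at a stage iff ≥ 1 DHS overlaps its promoter
window. With four stages, the non-all-absent presence/absence patterns
define the family of 15 pattern gene sets; all-absent genes are excluded.
Opening/closing uses the two endpoint stages (first → last): a gene
absent-then-present is opening, present-then-absent closing; region-level
calls use ≥ 1 bp overlap as cross-stage correspondence, the simplest
testable rule. Bivalency reuses the both-replicate rule on ChIP peaks per
mark: a gene whose promoter carries reproducible H3K4me3 and H3K27me3
peaks is bivalent.

## Expression dynamics

Counts are scaled by TMM-style factors: M-values are log2 ratios of raw
counts against a reference sample (upper quartile closest to the mean
upper quartile), genes with zeros excluded, double-trimmed (30% on M, 5%
on A), averaged with abundance weights √(x·r), and rescaled to geometric
mean 1. Taking M on raw counts means a factor absorbs relative depth as
well as composition; the effective library size is the factor times the
geometric-mean library size, and the abundance weights make the factors
exactly equivariant under scaling of any one library — so expression
values, `count / effective library size × 1e6 / (length/1e3)`, are
exactly depth-invariant. The display transform adds a pseudocount of 1
(`expression value + 1`) for log-scale plots.

The time-course test is the polynomial-regression core of a
maSigPro-style analysis, deliberately simplified to a single
full-vs-intercept F-test on `log(value + 1)` against stage time (E-day
values 12/13/14/16, honouring the unequal spacing; degree
min(3, stages − 1)), BH-corrected across genes with DEGs at FDR < 0.05.
The two-step stepwise selection of the original is omitted because only
the DEG list and the profile clusters feed downstream analyses. On 2000
null genes the raw rejection rate at α = 0.05 sits within 0.05 ± 0.02 and
BH passes at most a handful. DEG profiles (per-gene z-scored stage means)
are clustered by k-means with 25 restarts under a fixed seed into nine
temporal classes; k-means was chosen for determinism under a seed, with
the cluster count fixed at the analysis's nine profiles. Zero-variance
genes get p = 1 by convention; exact polynomial trends get p = 0.

Two auxiliary tests mirror the study's secondary comparisons: a
pooled-variance two-group t-test with BH q-values (microarray-style,
q < 0.05), and a twofold-change rule with pseudocount 1 for
single-replicate comparisons.

## Overlap statistics and GSEA

Gene-set overlaps are tested with Fisher's exact test (hypergeometric
tails; enrichment one-sided "greater" by default, with the two-sided
convention summing outcomes no more likely than observed). The sidedness
default is a package choice — enrichment is the question every matrix in
the analysis asks — and is recorded in the output. Overlap matrices apply
BH jointly across all cells, the most conservative defensible choice
when the source analysis does not state its multiplicity handling; raw p
is also reported.

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum: hit
increments ∝ |score|^weight (normalised), miss decrements 1/(N−m), ES the
maximal-magnitude deviation. The null permutes gene labels under a fixed
seed (the pipeline receives a precomputed ranking, so phenotype
permutation is not applicable); NES divides ES by the mean |ES| of
same-sign permutations and p is the same-sign tail frequency with the +1
continuity correction.

## Numerical and edge-case conventions

* Coordinates are 0-based half-open in all files (BED convention) and
  1-based closed inside `GRanges` objects; conversions happen only at I/O
  boundaries.
* Empty tracks give all-zero KDE profiles, not errors; empty DHS sets give
  all-zero feature fractions.
* Quota rounding uses largest remainders, so planted class counts always
  sum exactly to the gene count.
* k-means ties and restarts are controlled by the single fixed seed;
  duplicated profiles always co-cluster.
* Fisher tables with zero margins fall back to the whole tail (p = 1 for
  minimal overlap under "greater").

## Problem sizes

The validation analyses run at the default study size: 10 Mb genome, 1000
genes, 4 × 2 DNase tracks (~1.1e5 cuts each), 2 × 2 ChIP tracks, 8
RNA-seq samples; the exhaustive Fisher check enumerates every 2×2 table
with N ≤ 40, and KDE/GSEA oracle checks run on lists of up to 200 cuts /
50 elements. These sizes keep every planted effect measurable with large
margins while the full suite runs in a couple of minutes.

## Known limitations

* The Cornish–Fisher null corrects skewness but not kurtosis; at
  substantially smaller p or sparser backgrounds an exact compound-Poisson
  tail would be preferable.
* The F-test assumes homoscedastic Gaussian errors on the log scale; NB
  counts at very low means violate this, which shows up as reduced power
  for low-expression genes rather than inflated type-I error.
* Cross-stage region correspondence by ≥ 1 bp overlap can chain distinct
  elements through a shared wide DHS; gene-level calls, which drive all
  downstream statistics, are unaffected.
* The generator plants accessibility only at promoters and (optionally)
  enhancers, so distal-feature fractions of called DHSs are structurally
  near zero — unlike real DNase data, where distal DHSs dominate.
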