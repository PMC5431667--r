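---
title: "Detecting and classifying de novo CNVs across sampling time points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying de novo CNVs across sampling time points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longcnv)
```

## The problem

SNP genotyping arrays report, for every probe, a logR ratio: a normalized
log-scale intensity that is approximately 0 for the diploid state, negative
over deleted segments and positive over duplicated ones. When the same
subject is arrayed at three consecutive time points — blood samples taken
as an animal ages, or DNA from successive passages of a fibroblast culture
— copy number variants (CNVs) can be separated into those present
throughout the sampling period ("constant") and those absent at the first
sampling but detected later ("de novo"). `longcnv` implements that whole
workflow: per-sample quality screens, segmentation of each logR track into
CNV calls, cross-time-point matching and temporal classification, coverage
and rate statistics, gene/QTL annotation with enrichment tests, and qPCR
validation arithmetic. A synthetic-cohort generator stands in for real
array data so that every stage is testable end to end without downloads.

## Quality control

Three screens are provided, mirroring standard array-CNV practice.

* **Derivative log ratio spread** (`dlrs()`): the median absolute
  difference between adjacent-probe logR values, divided by \(\sqrt 2\);
  differences are taken only within chromosomes. For iid Gaussian noise of
  standard deviation \(\sigma\) the statistic estimates
  \(0.6745\,\sigma\). Samples are flagged with the Tukey rule
  (dLRs \(> Q_3 + 1.5\,\mathrm{IQR}\)); the rule needs at least four
  samples, below which nothing is flagged and a warning is raised. The
  flagging constant is exposed because "outlier" has no canonical
  definition in this setting.
* **Genomic waves** (`wave_metric()`): long-range logR undulations that
  correlate with local DNA composition. The metric is the absolute Pearson
  correlation between per-window median logR (1 Mb windows by default) and
  a per-window covariate — true GC content where available, or the
  simulator's wave covariate. A full GC-model regression is deliberately
  out of scope because the package bundles no reference genome; the
  windowed correlation screens for the phenomenon without correcting it,
  which matches a screening-only workflow.
* **PCA batch check** (`pca_batch_check()`): principal components of the
  marker-centered matrix, plus the mean silhouette width of each candidate
  batch factor (time point, subject) on the PC1–PC2 plane. Visual
  inspection of a score plot is thereby reduced to one number per factor;
  values near 0 mean no clustering. Sex-chromosome markers are removed
  before any of this (`exclude_sex_chromosomes()`), since single-sex
  cohorts make X/Y intensities uninformative for autosomal CNV calling.

## Segmentation

Each sample's logR track is segmented chromosome by chromosome under the
calling criteria: maximum pairwise segment p-value 0.005, at least 2
markers per segment, single-marker outlier removal, and segment means
filtered at \(\pm 0.35\) logR units to declare losses and gains
(`seg_params()`).

The search is a circular-binary-segmentation-style recursion
(`segment_chromosome()`): at each step the candidate inside-window
\([i, j]\) minimizing the total within-segment sum of squares (window
versus its flanks) is located, and the split is accepted only when a
pooled-variance t-test between inside and outside clears the criterion
after Bonferroni correction by the number of candidate windows scanned.
Two numerical points motivate this construction:

* A *single-breakpoint* recursion cannot detect a short CNV inside a long
  chromosome at all — the two-arm means differ by the shift diluted by the
  arm-length ratio, so a 5-marker event in a 400-marker chromosome never
  reaches significance at the first split. Searching windows rather than
  single breakpoints removes that blind spot.
* The selected window is the best of \(O(n^2)\) candidates, so its
  nominal p-value is strongly biased toward zero, and the window's *own*
  variance is biased low by the same selection. An uncorrected test
  over-splits pure noise badly. The pooled-variance statistic takes its
  scale mostly from the (unselected) outside markers, and the Bonferroni
  factor is the standard conservative bound for a maximum over dependent
  tests. Under the default noise model, pure-noise chromosomes of 200
  markers stay unsplit in essentially every replicate, while planted
  5-marker shifts of 0.6 logR units remain detectable at
  \(p \ll 0.005\).

After the recursion, a pruning pass enforces the stated criterion exactly:
adjacent segments whose two-sided Welch t-test p-value exceeds 0.005 are
merged, least-significant pair first, iterated to a fixed point. The Welch
(unequal-variance) form is used for this pairwise criterion because
segment sizes are typically very different; zero-variance segments are
handled by an exact-equality shortcut (p = 1 for equal constant segments,
0 for unequal ones). The output always partitions the chromosome, ties in
the window search break toward the leftmost candidate for determinism, and
on small instances the accepted partition attains the exhaustive
minimum-SSE partition among all partitions valid under the same pairwise
rule (verified in the test suite by direct enumeration).

**Outlier removal** (`remove_outliers()`) masks a marker when it deviates
from the running median (window 5) by more than 3 running-MADs while
neither neighbor lies on its side of the running median — an isolated
spike, not the edge of a genuine shift. Masked markers are excluded from
all segment statistics but spanned by the containing segment's
coordinates, so coordinates remain a partition of the map. An epsilon
floor on the MAD keeps flat regions from degenerating.

**Coordinates.** Marker indices are 1-based and inclusive internally;
exported intervals are half-open, with `start_bp` the first marker's
position and `end_bp` the last marker's position + 1, so lengths are
`end_bp - start_bp`. BED export shifts to the 0-based convention.

## Temporal classification

Calls from a subject's three samples are grouped into trajectories by
single linkage under a reciprocal-overlap predicate (`match_calls()`,
default fraction 0.5): two same-state calls on one chromosome are linked
when their overlap covers at least half of each. How repeated detections
of "the same CNV" should be identified across time points is genuinely
open — no universal rule exists — so the fraction is a parameter. By
default the predicate is evaluated on the *marker spans* covered by each
call rather than raw basepairs: array spacing is heavy-tailed, and a
boundary off by a single probe across a long inter-marker gap would
otherwise break a match that is essentially exact in probe space.

Each trajectory takes the union of its members' intervals (a conservative
choice for coverage accounting) and the OR of per-time-point presence,
then `classify_pattern()` maps the pattern: (1,1,1) constant, (0,1,1) de
novo at the 2nd and 3rd samplings, (0,0,1) de novo at the 3rd only, and
every other nonzero pattern inconsistent. Inconsistent trajectories —
disappearing events, plausibly mosaic fractions dropping below detection
— are retained in the output but excluded from all headline statistics.
The (1,0,1) gap pattern gets an extra diagnostic flag, since a clean
dataset should contain none.

Cohort statistics (`cohort_summary()`, `genome_coverage()`) include
per-class totals, the de novo fraction, per-subject counts, and cumulative
genome coverage: at time point *t*, the union length of all non-inconsistent
trajectory intervals first present at or before *t*, computed per
chromosome so overlaps are not double counted — monotone in *t* by
construction. The per-class coverage statistic is the median trajectory
length times the trajectory count (`coverage_statistic()`), and the
between-dataset de novo contrast is an exact two-sided binomial test of
one group's de novo count against the other group's fraction
(`denovo_proportion_test()`), two-sided by summing the probabilities of
all outcomes no more likely than the observed one. Division-corrected
rates divide the de novo count by the estimated number of cell divisions;
in vitro divisions are passages times average population doublings per
passage. Reported ratios round half away from zero (`round_away()`) to
match how such headline numbers are conventionally printed.

One published formulation of the binomial comparison is ambiguous (a
within-dataset reading of "de novo vs constant" near a 50:50 split cannot
be significant); the implementation tests the between-dataset contrast of
the two de novo proportions, which is the reading consistent with the
reported effect.

## Annotation and enrichment

`overlap_features()` reports every interval/feature pair sharing at least
one base (half-open semantics; the minimum shared length is a parameter).
`venn_partition()` gives the exact membership partition of up to four gene
sets. `qtl_class_enrichment()` counts, per trait class (Health, Meat and
carcass, Milk, Production, Reproduction, Exterior), the CNVs of each group
overlapping at least one QTL of the class — multiple QTLs of one class
within one CNV count once — and tests the de novo count against the
constant group's proportion with the exact binomial test; a continuity
floor of \(0.5/n\) keeps a degenerate null proportion inside (0, 1). The
null-proportion construction is a documented convention, since enrichment
by binomial test can be set up several ways. `geneset_enrichment()`
implements the standard hypergeometric over-representation layout
(C, O, E = Ck/N, R = O/E, upper-tail rawP, Benjamini–Hochberg adjP);
cross-species gene-name conversion is a user-supplied mapping, not a live
service.

## qPCR validation

`relative_quantity()` computes efficiency-corrected relative quantities
against a control sample (a pool of all first-time-point samples, taken as
diploid at every tested locus) with two normalizer genes: replicate Cq
values are averaged, the target's \(E^{\Delta Cq}\) is divided by the
geometric mean of the normalizers', and per-assay efficiencies are inputs
(default 2.0; estimating them from raw fluorescence curves is out of
scope). With perfect efficiency and stable references,
\(\log_2 RQ = -\Delta\Delta Cq\) exactly, and RQ is invariant to any
constant shift of all Cq values. Ratios of the later time points to the
first are thresholded at 0.75/1.25 (inclusive) for loss/gain — the
cutoffs are this package's defaults, chosen to sit halfway between the
diploid ratio 1 and the one-copy ratios 0.5/1.5 expected for a clean
heterozygous change. Agreement with array calls
(`qpcr_agreement()`) is the percentage of (assay, sample, time point)
pairs with identical direction-of-change status; direction agreement is
used because finer notions of concordance are not well defined when the
array reports a segment mean and the qPCR a ratio.

## The synthetic cohort generator

`sim_cohort()` emulates the structure of a ~50k-probe autosomal array
study. Defaults are the study conditions exercised by the test suite and
the acceptance benchmark:

| parameter | default | rationale |
|---|---|---|
| subjects × time points | 8 × 3 | in vivo cohort layout |
| chromosomes × markers | 8 × 400 | 3,200 markers keep a full 10-replicate benchmark under a minute while leaving every chromosome ~100× longer than a typical CNV |
| mean marker spacing | 50 kb (exponential) | ~50k probes over ~2.6 Gb; exponential spacing models a Poisson probe layout with realistic long gaps |
| noise sd | 0.15 logR | mid-range array noise; the dLRs of such tracks (~0.10) sits where passing arrays typically sit |
| loss / gain shift | −0.6 / +0.45 | typical Illumina one-copy magnitudes; both clear the ±0.35 filter with margin at the default noise |
| planted per subject | 14 constant, 4 + 9 de novo | the per-sample class averages of the in vivo cohort, with the de novo split following the reported 2nd&3rd : 3rd-only ratio |
| CNV length | 5–15 markers, uniform | short-CNV regime of array studies; 5 markers is the hardest case the benchmark must still detect |
| gain fraction | 0.05 | deletions dominate real array CNV sets (≈ 4% gains in vivo) |
| wave, outliers | off (0 amplitude / 0 rate) | switched on per test to exercise the wave metric and the masking path |

Planted CNVs are placed without overlap and with a 10-marker guard gap
within a subject so that distinct events remain separable by construction.
One layout is drawn per configuration and shared by all subjects (a
deterministic contract that makes cross-subject comparisons exact);
per-subject-per-time-point noise streams are derived from the single seed.
The optional wave is a long-period sinusoid in marker index — it
reproduces the wave phenomenon without requiring a reference genome's GC
track — and outliers are isolated ±1.0 spikes.

The generator does **not** model B-allele frequencies, mosaic (partial)
shifts, sex chromosomes, probe-specific noise, or spatially correlated
noise beyond the optional wave. Passing the benchmark therefore
demonstrates correct recovery of clean, full-magnitude events under
Gaussian noise — not performance on low-mosaic-fraction events or on
arrays with strong uncorrected waves, where real sensitivity will be
lower. The published noise level and true CNV magnitudes of any specific
dataset are not estimated here; the defaults are stand-ins.

## Benchmark results computed by the suite

The test suite and `scripts/acceptance.R` recompute (never hard-code):
the arithmetic of the headline ratios; the exactness of the binomial and
hypergeometric machinery against brute-force enumeration; the
segmentation fixed-point and exhaustive-DP optimality on ≤12-marker
instances; the pure-noise specificity (≥9/10 unsplit chromosomes); and
the end-to-end benchmark — ≥95% of planted CNVs recovered with the
correct temporal class over 10 cohort replicates (2,160 planted events),
with every subject's cumulative coverage curve monotone. Problem sizes
(3,200 markers, 10 replicates, 20 small oracle instances) were chosen so
the whole suite runs in about a minute on one core.

## Known limitations

* The segmentation objective is a reconstruction of a described-but-
  unpublished proprietary procedure; numeric identity with that
  software's output is not claimed, only the stated acceptance criterion
  (pairwise p ≤ 0.005, ≥2 markers, outlier removal, ±0.35 mean filter).
* The Bonferroni window correction is conservative; very short, very
  low-amplitude events that a permutation-calibrated scan might keep are
  lost. At the defaults this costs little (recovery ≈ 97–98%), and the
  trade is determinism and speed.
* Welch pruning at n = 5 markers has df ≈ 4, so a genuine short CNV with
  unluckily large within-segment variance is occasionally merged back;
  this, not discovery, dominates the residual benchmark misses.
* Trajectory matching assumes boundary stability across time points;
  heavily fragmented calls at one time point can split a trajectory.
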