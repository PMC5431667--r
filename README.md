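# longcnv

Longitudinal copy-number-variant (CNV) analysis from SNP-array logR
signals: call CNVs per sample, match them across three sampling time
points of the same subject, and classify each as **constant** (present
throughout) or **de novo** (absent at the first sampling, detected
later).

The package is aimed at array-CNV studies with a prospective design —
e.g. blood samples of the same animals arrayed as they age, or DNA from
successive passages of cell cultures — where the question is not "which
CNVs does this genome carry" but "which CNVs *appeared* during the
sampling period, and at what rate".

## What it computes

For each sample the logR track is segmented chromosome by chromosome with
a circular-binary-style search: the marker window most distinct from its
flanks (minimum total within-segment sum of squares) is split out when a
multiplicity-corrected t-test clears the maximum pairwise segment p-value
(default 0.005), segments need ≥ 2 markers, isolated spikes are masked by
a running-median/MAD rule, and adjacent segments are re-merged to a fixed
point of the pairwise Welch criterion. Segments with mean logR < −0.35
become loss calls, > +0.35 gain calls.

Within a subject, same-state calls are grouped across time points by
single-linkage reciprocal overlap (default 0.5, evaluated on marker
spans) and the presence pattern over the three samplings is classified:

| pattern (t1,t2,t3) | class |
|---|---|
| 1,1,1 | constant |
| 0,1,1 | de novo (2nd & 3rd) |
| 0,0,1 | de novo (3rd only) |
| anything else | inconsistent (excluded from headline statistics) |

On top of the trajectories the package computes per-class totals and the
de novo fraction, cumulative genome coverage per subject and time point
(interval unions, monotone over time), the median-length × count coverage
statistic, exact binomial comparisons of de novo proportions between
datasets, division-corrected de novo rates, gene/QTL overlap annotation,
QTL trait-class binomial enrichment, hypergeometric gene-set enrichment
(C/O/E/R/rawP with Benjamini–Hochberg adjP), and qPCR relative-quantity
validation against a pooled first-time-point control with two normalizer
genes.

A synthetic cohort generator (`sim_cohort()`) emulates 50k-array logR
matrices — exponential marker spacing, Gaussian noise, optional
GC-style waves and outlier spikes, and planted CNVs with configured
temporal classes — so the whole pipeline is testable without any
external data. Sample QC (derivative log ratio spread, wave metric, PCA
batch check with silhouettes) is included.

## Worked example

```r
library(longcnv)

res <- run_report(sim_config(seed = 1))
res$summary
#> Longitudinal CNV cohort summary
#>   trajectories: 218 (110 constant, 105 de novo [32 at t2&t3, 73 at t3], 3 inconsistent)
#>   de novo fraction: 49%
#>   per subject: 14 constant / 13 de novo on average
#>   losses/gains: 207/8; median length 442 kb
res$recovery
#> $n_truth
#> [1] 216
#> $n_recovered
#> [1] 211
#> $fraction
#> [1] 0.9768519
```

The default configuration plants 14 constant and 13 de novo CNVs per
subject in an 8-subject, 3-time-point cohort (noise sd 0.15, loss/gain
shifts −0.6/+0.45). The summary shows the pipeline's trajectory counts —
here 110/105/3 constant/de novo/inconsistent against the planted
112/104/0 — and `recovery` scores how many planted CNVs were recovered
with the correct temporal class (97.7% in this run). Headline statistics
are available as plain functions on counts you supply:

```r
denovo_proportion_test(107, 218, 21, 85)   # 5.85e-06: the two cohorts differ
round_away(division_corrected_rate(107, 120), 1)  # 0.9 de novo CNVs/division
signif(coverage_statistic(rep(36e3, 107)) / 1e6, 2)  # 3.9 Mbp
```

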