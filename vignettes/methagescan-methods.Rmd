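---
title: "Detecting age-associated methylation change in paired methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-associated methylation change in paired methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methagescan)
```

## The problem and the model

Sperm DNA methylation drifts with a man's age, and because the germ line is
the only tissue transmitted to offspring, regions that drift *consistently*
across individuals are candidates for paternal-age effects. The design that
motivates this package is a paired one: the same donors sampled twice,
roughly a decade apart, assayed on a 450K-style beta-value array
(`beta = M / (M + U)`, the fraction methylation at a CpG). Paired sampling
removes between-donor baseline differences, which dwarf the aging signal —
typical drift is only a few tenths of a percent methylation per year.

The scanner models a candidate region as a 1000-bp window over the probe
manifest. Within a window, the observation unit is the probe-level paired
difference (aged minus young), pooled over probes and donors. For a window
with 5 probes and 17 donors that is 85 differences. Three statistics
summarise a window:

* **Pseudo-median** (Hodges–Lehmann): the median of all Walsh averages
  `(x_i + x_j)/2`, `i <= j`. It is computed for the per-sample window means
  of each age group (`pm_young`, `pm_aged`) and for the pooled paired
  differences. The pseudo-median resists the outliers that single noisy
  probes produce.
* **log2 ratio** `log2((pm_aged + eps)/(pm_young + eps))`, `eps = 1e-6`,
  the magnitude filter. At a baseline of 0.5, `|log2| = 0.2` is an absolute
  change of roughly 0.05–0.07 — about a 10% relative change.
* **Wilcoxon signed-rank** two-sided p on the pooled differences: zeros are
  dropped, ties get average ranks, and the null distribution is exact (by
  dynamic-programming convolution over the doubled rank weights, which is
  valid with ties) up to 25 nonzero differences, a tie-corrected normal
  approximation with continuity correction beyond.

P-values are corrected with the Benjamini–Hochberg step-up across **all**
candidate windows. Significance requires `q <= 1e-4` and `|log2| >= 0.2`;
q-values are also reported on the display scale `-10*log10(q)` (40
corresponds to q = 0.0001, 20 to 0.01, 13 to 0.05). Each window then passes
through two per-window checks: a confirmatory paired t-test on per-donor
window means (reported, never a filter) and an ordinary least-squares
regression of the per-sample window mean on age at collection — windows
with regression p > 0.05 are excluded. The regression slope is reported
both as fraction/year and as percent/year (x100). Finally, overlapping or
book-ended significant windows of the same direction merge into regions.

### Why probe-level pooling

With 17 donors and one value per donor, the smallest achievable two-sided
signed-rank p is `2/2^17 ~ 1.5e-5`, which cannot survive BH at
`q <= 1e-4` across thousands of windows. Pooling probe-level differences
(~85 observations) makes the stated threshold attainable while still
testing the same null — no consistent within-donor change — and reflects
how a windowed scanner aggregates evidence. This is a declared design
choice, as is the window enumeration: one candidate anchored at each probe,
spanning `[pos, pos + 1000)`, with candidates whose probe set nests inside
an earlier candidate's set collapsed onto it. Anchoring avoids inventing a
step size, and the post-hoc merge of significant windows reproduces
regions that are typically a little under the nominal window size.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `window_size` | 1000 | bp | candidate window span |
| `min_probes` | 3 | probes | minimum probes per candidate |
| `q_max` | 1e-4 | — | BH q threshold (display value 40) |
| `min_abs_log2` | 0.2 | — | magnitude threshold |
| `regression_alpha` | 0.05 | — | age-regression retention level |
| `shore_flank` | 2000 | bp | CpG-island shore width |
| `colocalization_margin` | 1000 | bp | edge-to-edge track distance |
| `promoter_window` | 1000 | bp | promoter span upstream of TSS |
| `age_cutoff` | 45 | years | young/aged boundary (45 itself is aged) |
| `min_fraction` | 0.10 | — | consensus CpG support rule |
| `cluster_window`, `cluster_min_marks` | 1e5, 2 | bp, marks | chromosomal cluster calling |

All thresholds are configuration, not constants; `pipeline_config()`
validates them and rejects unknown keys.

## The synthetic cohort

`synthetic_config()` defaults define the study conditions every test runs
under: 17 donors, first collection at 23–56 years, second 9–19 years later;
~10,000 candidate probe clusters of 5 probes across 22 chromosomes, 139
planted hypomethylation and 8 planted hypermethylation regions; Gaussian
probe noise with SD 0.02; per-donor offsets (SD 0.01); cluster baselines
0.2–0.6 (hyper clusters 0.2–0.35, so gains stay modest, as aged-gain
regions start from low-methylation contexts and clamping to [0, 1] never
bends the planted linearity).

A planted probe follows
`beta = base + donor_offset + drift * age + noise`, so the paired
difference is exactly `drift * interval` and the per-sample window mean is
linear in age — which is what the regression filter assumes. `base` is
shifted by `-drift * mean(young age)` so the level at first collection
matches the sampled baseline. Planted drift magnitudes are drawn from
0.0008–0.0095 fraction/year and raised, per region, so that even the
shortest-interval donor reaches `|log2 ratio| >= 0.3` at the aged
timepoint (`planted_log2_min = 0.3`); set it to `NULL` to study weaker
effects. Inter-cluster gaps of at least 6 kb guarantee that windows,
2-kb shores and 1-kb co-localization margins of different clusters never
interact, which is what makes exact-recovery tests meaningful.

The generator also emits CpG-island/nucleosome/histone tracks and gene
models whose placement probabilities differ by cluster class (hypo clusters
near retained nucleosomes and shores, hyper clusters at islands), targeted
bisulfite read tables drawn from per-amplicon beta-binomial mixtures (three
default amplicons reproduce the observed population-shift patterns: deep
hypomethylation deepening, a unimodal shift, and a bimodal young profile
collapsing with age), a gene–disease table with one optionally enriched
disease, and global LINE-1-style values with a planted linear trend.
Everything derives deterministically from one master seed through per-
artifact sub-seeds; identical configurations give bit-identical outputs.

What the generator does **not** emulate: Infinium dye/chemistry biases,
batch effects, spatially varying probe density, correlated noise between
neighbouring probes, bisulfite conversion failure, or sequence-level reads.
Passing recovery tests therefore demonstrate the correctness of the
statistics and plumbing under the declared noise model, not performance on
raw array data — on real data the QC filter, normalisation and batch
correction upstream of this package do substantive work.

## Numerical choices and degenerate inputs

* Exact signed-rank p-values use the convolution of doubled (possibly
  half-integer, tie-averaged) ranks — `O(n * sum(ranks))`, exact for any
  tie pattern. All-zero difference vectors give p = 1, flagged.
* `transform_fdr()` floors q at 1e-30 (flagged) so q = 0 cannot produce an
  infinite display value; the transform is strictly decreasing.
* The log2 ratio's `eps = 1e-6` guard keeps zero pseudo-medians finite.
* Paired t-tests and the global paired test report `NA` with a
  `defined = FALSE` flag when differences have (numerically) zero variance.
* Windows with zero age variance cannot be regression-filtered and are
  dropped with a warning.
* The QC rule is implemented exactly as specified for this assay — remove
  probes with QC p **below** the threshold — but a `polarity` flag flips it
  to the usual detection-p convention, since the two conventions are easy
  to confuse and real manifests differ.
* Consensus CpG counting takes the largest read length supported by at
  least 10% of reads with *exactly* that length; an `at_least` variant is
  available. If nothing reaches 10% the modal length is used, flagged.
  Reads longer than the consensus are discarded, not truncated.
* Cluster permutation p-values use the add-one estimator, bounded below by
  `1/(n_permutations + 1)`.
* Spline smoothing of read-population profiles is display-only; statistics
  always use raw bins.

## Problem sizes

The default test-and-verification scale is the full design: 100,000 probes,
34 samples, 10,000 candidate windows (about 15 s for a complete scan on one
core). Calibration checks use reduced universes — 300-cluster null cohorts
over 20 seeds for specificity, 100 seeds for chi-squared calibration — so
that the whole suite completes in a few minutes.

## Known limitations

* The BH universe is all candidates passing `min_probes`, with the
  regression filter applied after significance. Filtering before BH would
  change q-values; the order implemented is the one the pipeline declares.
* Region-level direction is inherited from window-level calls; a region
  cannot mix directions (opposite-direction windows never merge).
* Co-localization distance is edge-to-edge; a midpoint variant would score
  long regions differently.
* The disease-enrichment background is the set of genes with at least one
  association, not the whole genome; with a whole-genome background the
  same counts are far less surprising, which is why both views matter.
* Exact recovery of the planted counts depends on the planted effect
  clearing the thresholds by a margin; with `planted_log2_min = NULL` and
  small drifts the scanner's power drops smoothly and counts become
  stochastic.

## A minimal run

```{r demo, eval = FALSE}
res <- demo_pipeline(seed = 7)
res$scan$log
head(res$scan$regions)
res$enrichment
```
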