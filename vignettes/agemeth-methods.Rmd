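---
title: "agemeth: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{agemeth: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the measurement model behind MeDIP-seq methylation scores,
the differential test, the permutation hotspot analysis, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want written down.

## 1. Measurement model

MeDIP-seq read density over a locus is, to first order, proportional to
the amount of methylated DNA captured there, which itself grows with the
local density of CpG dinucleotides. `agemeth` works throughout in 50 bp
bins (0-based, half-open coordinates everywhere; BED dialects on disk).
Two quantities are attached to each bin:

* the **coupling factor** `C_b`: the number of CpGs within 700 bp of the
  bin centre. 700 bp is the scale over which a captured fragment's CpGs
  can contribute signal to a bin, i.e. roughly the upper fragment length
  of a MeDIP library;
* the **methylation score**
  `score = (count / (library_size / 1e6)) / max(C_b, 1)` — counts per
  million divided by the coupling factor. A fragment contributes one
  count, to the bin holding its midpoint ("not extended": the sequenced
  fragment interval is used as given; midpoint binning avoids the length
  bias of overlap binning). The floor of 1 on the divisor means bins with
  no CpG in reach are *flagged* (`has_cpg = FALSE`) rather than divided
  by zero or inflated; a `normalize = "raw"` mode bypasses normalization.

The exact normalization inside historical MeDIP toolchains is not
uniquely defined (probit-calibrated variants exist); the formula above is
deliberately simple, declared, and used consistently — it is "rms-like",
not claimed identical to any external implementation.

### Group comparisons

Global comparisons are restricted to bins that contain at least one CpG
and carry at least one fragment in every compared sample, so that the
compared distributions describe the commonly observed methylome. The
per-group mean, a two-sample Kolmogorov–Smirnov test on the group-pooled
score distributions (two-sided; asymptotic p, exact when both pools have
fewer than 50 values), and the percent change
`100 * (mean_B - mean_A) / mean_A` are reported, plus five-number
summaries for box plots. CGI-level comparisons first average each
island's bins per sample, then compare islands covered in every sample.

## 2. DMR calling

Candidate regions ("bump-list") are maximal runs of adjacent bins whose
summed count over the two compared cohorts is nonzero, kept when the sum
reaches 10 reads. Testing happens at the region level, not the bin level.

Counts are modelled as negative binomial:

* **size factors** by median-of-ratios over regions with all-positive
  counts (geometric-mean-centred so their product is 1; total-count
  fallback, with a message, when no such region exists);
* **dispersion** in a *fit-only* sharing mode: per-region
  method-of-moments estimates (pooled within-group variance of normalized
  counts, with the shot-noise term `q * mean(1/sf)` subtracted) are
  regressed on the region mean with the trend `alpha = a0 + a1 / mean`
  by unweighted least squares, and every region is assigned its fitted
  value only, floored at 1e-8. Sharing the trend instead of taking
  per-region maxima trades robustness at low replication (n = 3 per
  group) against sensitivity to genuinely noisy regions; with
  homoscedastic biological noise the trend is the right object. Without
  replication the dispersion falls back to the floor (Poisson-like);
* **test**: conditional on a region's total count, the two-sided p-value
  sums the probabilities of all allocations of that total between the two
  group sums that are no more likely than the observed one (a `1 + 1e-7`
  relative tolerance guards the equality comparison against floating
  error). Group-sum distributions use `mu = q * S_g` and
  `var = q * S_g + alpha * q^2 * sum(sf^2)`, collapsing to Poisson when
  `var <= mu`. As `alpha -> 0` this reproduces the conditional binomial
  exact test, which the test suite checks against an independent
  enumeration oracle.

Fold changes are `log2((mean_B + 0.5) / (mean_A + 0.5))` on normalized
group means; the 0.5 pseudocount keeps zero-count groups finite.
Benjamini–Hochberg FDR is controlled over all tested regions; records
with FDR < 0.2 are reported as DMRs, direction taken from the fold sign
(with respect to the older group). A per-sample, row-scaled-to-[0,1]
region score matrix over all groups (including intermediate ones) is
emitted for heatmap display of progressive change.

## 3. Hotspot permutation test

DMRs are placed into non-overlapping 100 kb windows anchored at position
0 of each chromosome (a fixed tiling, not a sliding scan; assignment by
region midpoint, half-open so a midpoint at exactly 100 000 falls into
the second window; ties for the maximum resolve to the first window in
chromosome order and are flagged). The null distribution draws equally
many regions from the bump-list uniformly *without replacement* — the
bump-list is a set of regions, not a weighted population — and the
empirical p-value is `(1 + #{null max >= observed max}) /
(n_permutations + 1)`, so p = 0 is unattainable and 1/1001 is the floor
at 1000 permutations. A `strict_greater` flag switches the exceedance
rule to `>`; `>=` is the default because it is the conservative reading.

Because the maximum window count is a small integer, the empirical p
lives on a coarse lattice: it is a *valid* p-value (its low tail never
over-rejects, which the test suite verifies across 50/100/200 kb
windows), but it is not smoothly uniform under the null — a
Kolmogorov–Smirnov comparison against U(0,1) will reject essentially
always, in any design where the max statistic takes a handful of likely
values. The acceptance suite contains both checks; the uniformity one
documents this limitation rather than a defect of the machinery.

## 4. Feature enrichment and gene association

A region belongs to a feature class (CGI, shore, exon, intron,
intergenic) iff it overlaps at least 1 bp of it; a region may belong to
several classes. For each direction and class, the 2×2 table contrasts
DMRs of that direction against all other bump-list regions, and a
one-sided (enrichment) Fisher's exact test is applied — only enrichment
is of interest, depletion of a small DMR set is uninformative. Shores
extend 2000 bp on each side of an annotated island, clipped at chromosome
ends and island boundaries. Genes within 100 kb of a DMR (minimum
interval distance, 0 for overlap, boundary inclusive) are listed nearest
first, ties broken by gene id.

## 5. The synthetic-data generator

The generator exists so that every downstream stage has a testable ground
truth. It emulates, per sample:

* a genome of 2 × 1 Mb with background CpGs at 0.008/bp and 40 CpG
  islands (~2 kb, 0.15 CpGs/bp), genes with exon/intron structure, and
  the derived shore/intergenic annotation (every base belongs to at least
  one class);
* a latent methylation surface: lowly methylated islands (0.25) in a
  highly methylated background (0.75), log-normal spatial heterogeneity
  (sdlog 0.1) shared by all groups; the oldest group loses 5% of non-CGI
  methylation; intermediate groups sit halfway (the observed change is
  progressive and directional, but no functional form is established, so
  linear interpolation is the least-assumption choice);
* planted DMRs: 20 regions of 800 bp at local CpG maxima (at least 10
  CpGs inside, flanks CpG-poorer), kept at least 1 kb apart so each forms
  its own candidate region; 8 hypermethylated ones spread across a single
  100 kb window (the hotspot), the rest split between hyper (half inside
  CGIs, mirroring age-related island gains) and hypo. Baselines are 0.30
  (hyper) and 0.70 (hypo), shifted by `2^(+/-1.5)` in the oldest group;
* fragment capture: midpoints drawn per bin with probability
  proportional to `(CpGs within 200 bp)^1.8 x latent methylation`, then a
  uniform offset; lengths Normal(200, 30) truncated to [50, 400]
  (a 190–200 bp MeDIP library); input controls are uniform. Biological
  replicate noise multiplies the capture weights by log-normal factors
  (sdlog 0.1) drawn per sample on 2 kb blocks, giving region counts a
  negative binomial overdispersion of about 0.01. Small configured
  fractions of pairs are improper (1%), low-quality on both reads (2%) or
  exact duplicates (1%) so the filtering rules are exercised. Every
  sample has its own RNG stream derived from `(master seed, sample id)`,
  so adding a replicate never reshuffles the others and identical
  configurations are byte-identical.

### Why these defaults: an identifiability argument

With a fixed per-replicate fragment budget, depth normalization makes a
*uniform* multiplicative methylation loss invisible: scaling every bin's
capture weight by 0.95 leaves the multinomial sampling probabilities
unchanged. A global loss is only measurable relative to an internal
reference that does not shift. In real MeDIP data that reference is the
CpG-dense, lowly methylated island compartment (exempt from the non-CGI
loss); the generator reproduces this by giving islands a substantial
share of pull-down mass (the 1.8 capture exponent and island CpG density
do this), while the coupling division keeps island bins from dominating
the bin-level mean. The measured percent change is therefore an
*attenuated* version of the latent −5% — the design analysis predicts,
and the recovery tests observe, roughly −3 to −5% — exactly the kind of
attenuation a depth-normalized assay imposes. Likewise the count-space
fold change of a planted DMR is diluted by the non-DMR bins merged into
the same candidate region, which is why the latent effect default is 1.5
log2 units (≈2.8-fold) to produce ≈2-fold region counts.

### What the generator does not emulate

No base-level sequences (and hence no sequencing errors or mappability
structure), no bisulfite chemistry, no fragment-length bias in capture
efficiency, no copy-number or batch effects, and no correlation between
methylation and gene expression. Passing recovery tests therefore show
that the pipeline's statistics behave correctly under the stated
generative assumptions — not that they are robust to every artefact of
real libraries.

## 6. Calibration properties and known limitations

* **Null DMR p-values** are near-uniform-to-conservative: across null
  simulations the fraction of regions with p < 0.05 stays at or below
  0.05–0.075 (the conditioned NB test is conservative at low counts).
* **Pooled KS comparisons are not a calibrated test** at desk scale. Two
  effects pull in opposite directions: bins are heterogeneous, so pooling
  them is stratified rather than iid sampling and the two-sample KS
  becomes conservative; and scores are counts on a per-sample lattice
  (count / coupling / library size), so small library-size differences
  offset otherwise-identical lattices between groups, which the
  asymptotic KS reads as signal and over-rejects. There is no honest
  parameter choice between the regimes, so the null-calibration check for
  the pooled KS is retained in the acceptance suite as a documented
  failure. The KS test remains useful as a *detector* of large shifts
  (its intended role here); its p-values should not be read as exact
  under the null.
* **Empirical permutation p-values are lattice-valued** (see §3): valid,
  conservative at the tail, but not smoothly uniform.
* The **enrichment score** reported by the QC stage is a simple
  observed/expected CpG density ratio; it is internally consistent
  (input-like samples score ≈1) but not numerically comparable to scores
  from other toolchains.
* The between-replicate correlation windows pool the 5-read minimum over
  the two samples by default (`min_reads_mode = "sum"`); a per-sample
  (`"each"`) mode is provided, as the convention differs between tools.
* Whether a low-correlation replicate should also be excluded from DMR
  calling is a study-level decision; the pipeline exposes
  `exclude_samples` in the run configuration and takes no position.

## 7. Problem sizes used by the test and acceptance suites

Unit tests run on toy genomes (≤ 100 kb) with exhaustive or closed-form
oracles. End-to-end statistical checks use the generator's default scale
(2 × 1 Mb, 3 replicates per group, 2e5 fragments per replicate) for
headline detection and recovery (5 seeds), and reduced null designs
(single chromosome of 200–500 kb, 2–3 replicates, 3e4–1e5 fragments) for
the 200-seed calibration experiments, chosen so the full suite completes
comfortably on a single CPU while keeping every region-level test at
realistic per-region counts.
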