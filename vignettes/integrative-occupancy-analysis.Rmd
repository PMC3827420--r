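---
title: "Integrating TF occupancy with knockout transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating TF occupancy with knockout transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipxpr)
```

## The analysis this package implements

A recurring design in regulatory genomics profiles a transcription factor
(TF) twice: ChIP-seq maps where the factor binds, and expression profiling
of knockout versus wild-type cells shows which genes care. Neither
experiment alone identifies direct targets — binding without an expression
consequence may be incidental, and expression changes without binding may be
secondary. The integration this package automates defines, per cell type and
activation state:

* **bound genes** — genes whose regulatory domain contains at least one
  ChIP peak;
* **motif-bearing bound genes** — the subset whose peak(s) contain at least
  one occurrence of the factor's consensus recognition sequence (for RUNX
  family factors, TGYGGY: the variants TGTGGT, TGTGGC, TGCGGT, TGCGGC),
  evidence that binding is direct;
* **responsive genes** — genes passing the knockout differential-expression
  filter (fold change, p-value, above-background signal);
* **regulated genes** — responsive ∩ motif-bearing bound: the direct-target
  call.

Around this core sit the supporting analyses the same study design needs:
a peak caller for tag libraries, peak–gene association with TSS-distance
binning, cross-sample and cross-state occupancy comparisons, motif and
motif-module enrichment against genomic background, hypergeometric
statistics for cross-list overlaps, and pre-ranked GSEA linking binding to
expression change globally. Every stage runs on synthetic data with planted
ground truth, so the pipeline's sensitivity and specificity are measured,
not assumed.

## Peak calling: windowed Poisson test with a dynamic local lambda

Tags are counted in sliding windows (300 bp, step 100 bp). Each window's
count is tested against a Poisson null whose rate is the *maximum* of the
genome-wide control rate and the control rates in 1 kb / 5 kb / 10 kb
windows centred on the test window — the dynamic-lambda idea that lets a
control library absorb local biases. Libraries are equalised by scaling the
larger to the smaller: when the control is deeper, lambda is scaled down by
the depth ratio; when the treatment is deeper, treatment counts are scaled
down and the upper tail is evaluated through its continuous gamma
continuation `P(Pois(λ) ≥ k) = P(Gamma(k) ≤ λ)`. Windows at
p ≤ 10⁻⁵ are merged when closer than 100 bp; the summit is the
tag-densest position.

One numerical choice matters at desk-scale depth. With a control of a few
tags per kb, the raw 1 kb rate estimate is noisy, and taking a maximum of
noisy estimates biases lambda upward enough to mask genuine peaks. Local
rates are therefore shrunk towards the genome-wide rate with
`lambda_pseudo_bp` (default 2000) base pairs of pseudo-counts:
`rate = (count + rate_bg · w0) / (width + w0)`. On a uniform synthetic
control this removes essentially all of the noise penalty (measured planted-
peak sensitivity rises from ~0.96 to ~0.98 at 20 expected tags per window)
while wide, genuine local excesses still raise lambda. On real data with
strong sub-kilobase control artefacts the shrinkage halves the apparent
local rate; lower `lambda_pseudo_bp` if that regime matters.

The caller is a deliberately minimal re-implementation of the cited idea:
no fragment-shift model, no duplicate filtering, no sample-swap FDR. Peak
BEDs from a full caller are accepted by every downstream stage.

## Peak–gene association: basal-plus-extension domains

Each gene receives a strand-oriented basal window around its TSS (5 kb
upstream, 1 kb downstream by default) extended on both sides to the nearest
neighbouring basal window, capped at 1 Mb from the TSS and at chromosome
ends. A peak is assigned to every gene whose domain contains the peak
midpoint — in gene-dense intergenic regions that is legitimately two genes,
which is why a study can report more bound genes than bound regions. The
midpoint (not the summit) anchors both membership and the unsigned
TSS-distance, binned at 1 / 5 / 50 kb; a nearest-TSS-only mode is available
for sensitivity analyses. Genes with several annotation records per symbol
collapse to the longest before gene-level overlap arithmetic.

## Motif scanning and modules

Consensus motifs are IUPAC strings compiled to character-class regular
expressions and scanned with a zero-width lookahead, so overlapping
occurrences are all reported; both strands are scanned and an `N` in the
sequence matches only the `N` code. The scanner is intentionally simple
enough to verify exhaustively: the test suite holds it equal to a naive
position-by-position oracle over a thousand random (sequence, motif) cases.

Enrichment is a Z-score: observed occurrence totals against the mean and sd
of totals over B (default 100) independently sampled, length-matched
background region sets placed outside the observed peaks. A two-motif
*module* is a pair of occurrences in the same region with an edge-to-edge
gap of at most 50 bp (overlap counts as gap 0; a same-motif module needs two
distinct hits). Module enrichment per peak partition (resting-unique /
shared / de novo) is a density-per-kb fold over matched background. The
default partner consensi are published cores — ETS `MGGAA`, AP-1
`TGASTCA` — standing in for proprietary position-weight matrices; all are
configurable, and PWM scoring is out of scope.

## The differential-expression filter

The filter reproduces the microarray-era rule: a gene is responsive when
its linear fold change (from the difference of log2 group means, i.e. a
geometric-mean ratio) reaches 1.5, its two-sided p-value is below 0.05, and
its signal exceeds a platform background floor in at least one array. No
multiple-testing correction is applied by default, matching the rule being
reproduced; `de_config(adjust = "BH")` provides an FDR mode.

The p-value comes from a pooled-variance two-sample t test (the two-group
ANOVA a commercial suite computes). With three replicates the Welch
correction spends a degree of freedom the design cannot afford: measured on
40,000 simulated genes at a true 2-fold effect and 0.25 log2 replicate sd,
Welch detects 87.6% of effects while the pooled test detects 93.8%, with
both calibrated under the null (raw p ≤ 0.05 rate 0.051). Welch remains
available via `de_config(test = "welch")` for heteroscedastic designs.
Zero-variance noiseless fixtures get a p floor of 10⁻¹² and a flag, so
deterministic test data classify deterministically.

## Integration statistics

Associations between two gene sets in a common universe use the standard
2×2 machinery: Pearson chi-square without continuity correction, and a
two-sided Fisher exact p summed from hypergeometric point masses not
exceeding the observed table's mass. Cross-list overlap significance uses
the expected-by-chance count n₁·n₂/N and the exact hypergeometric upper
tail P(X ≥ k) (no normal approximation; a seeded Monte-Carlo cross-check is
provided). For lists from different array platforms the honest universe is
the intersection of the platforms' gene universes; the universe size is a
parameter everywhere, never an assumption. Direction concordance and the
printed-style ratio/percentage summaries (`summarize_ratios`) round the way
summary text prints — ratios to one decimal, percentages to integers — while
full precision is kept in the returned values.

## Pre-ranked GSEA

Genes are ranked by absolute linear fold change (descending; ties keep
stable input order by default, or gene-id order for shuffle-invariance).
The enrichment score is the signed extremum of the weighted running sum:
hits add |w|^p normalised over hit weights (p = 1 by default; p = 0 recovers
the unweighted Kolmogorov–Smirnov-style statistic), misses subtract
1/(N − N_hit). The null is built from random same-size gene sets (the
standard choice for pre-ranked mode, where no sample labels exist to
permute); NES divides the ES by the mean |ES| of same-sign null values and
the nominal p is the same-sign null fraction at least as extreme. Null
evaluation uses an extremum-only O(hits) evaluator — exact, and held equal
to the full running-sum profile and to an independent reference
implementation in the tests — which makes 500 × 1000-permutation null-
calibration runs affordable. Note that with steeply decreasing weights the
null ES distribution is legitimately skewed positive; only near-flat
weights centre it at zero, which is exactly why NES normalises each sign
separately.

## The synthetic study and what it does (and does not) show

`simulate_study()` emulates a two-cell-type × two-state design on one
shared toy genome (2 × 1.7 Mb, uniform base composition): 300 genes on a
jittered grid with alternating strands, 200 peaks per sample with lengths
N(300, 60) clipped to [200, 500], a 0.62 cross-cell-type overlap at rest
built by copying that fraction of cell-A peaks into cell-B with ≤40 bp
jitter, 60% of resting peaks maintained (jittered) into the activated state
plus de novo peaks in a disjoint offset window, a RUNX variant overwritten
into 90% of peak loci (uniform variant and strand), a histone-mark-like
track covering 85% of cell-A resting peaks, tag libraries at 0.0067
tags/bp background with 10× enrichment in peaks (≈20 expected tags per
fully covered window) and a 1.25× deeper control, and per-condition WT/KO
expression (3 replicates, 0.25 log2 noise) with 2–4-fold effects planted
in 30% of bound genes, 60% of them down-regulated in the knockout, plus 8%
of genes forced below the background floor.

Three deliberate idealisations keep the planted truth *exact* rather than
approximate, and they bound what passing tests prove:

* **Gene spacing.** TSSs sit ≥10.6 kb apart so basal windows never overlap
  and a basal-placed peak maps to exactly one gene. Real genomes have gene
  deserts and overlapping basal windows; the two-gene assignment path is
  exercised by constructed fixtures instead.
* **Motif-sterilised peaks.** After planting, incidental consensus matches
  inside peak loci are mutated away (a 6-mer family arises by chance in
  ~40% of 300 bp regions, which would otherwise swamp the plant rate).
  Genomic background *outside* peaks is untouched, so background-based
  Z-scores stay meaningful.
* **Unshifted tags.** Tags are drawn directly in peaks with no fragment-
  shift geometry, matching the caller's no-shift model.

The generator therefore demonstrates algorithmic correctness and
calibration under known truth — not performance on real chromatin, with its
mappability structure, copy-number artefacts, heteroscedastic arrays and
correlated probes.

Planted effects start at 2-fold rather than the filter's own 1.5 cutoff:
a true 1.5-fold effect at 0.25 log2 noise and n = 3 sits at the detection
boundary by construction (observed fold change falls below the cutoff half
the time), so recovery benchmarks there measure coin flips, not code.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; `run_pipeline()` derives per-stage
seeds from one global seed and identical (config, seed) pairs give
byte-identical reports. The bundled benchmarks use desk-scale sizes chosen
to keep a full run in minutes on one core: the default study above, a 2 Mb
single-chromosome genome with ~60 planted peaks for caller recovery, 2000
genes for the DE filter benchmark, and 500 replicates × 1000 permutations
for GSEA null calibration. `scripts/acceptance.R` re-runs all of them from
scratch at a caller-supplied seed.

## Known limitations

* The peak caller is pedagogical: no fragment-shift estimation, duplicate
  filtering or paired-end support; use a full caller for real libraries.
* Consensus (not PWM) motif models; de novo motif discovery is out of
  scope.
* The regulated-gene definition inherits the raw-p filter of the design it
  reproduces; treat regulated-set sizes as rule outputs, not FDR-controlled
  discoveries.
* Background sampling for Z-scores assumes the genome outside peaks is an
  acceptable null; on real genomes a matched-composition background is
  often preferable.
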