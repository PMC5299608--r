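---
title: "Methods: expression profiling of medullary thyroid cancer by RET mutation class"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression profiling of medullary thyroid cancer by RET mutation class}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcret)
```

## The scientific problem

Medullary thyroid cancer (MTC) arises from thyroid parafollicular C cells
and is driven, in most cases, by activating mutations of the *RET*
receptor tyrosine kinase: germline mutations in hereditary disease,
somatic mutations in a large fraction of sporadic tumours. Mutations in
the cysteine-rich extracellular region (exons 10–11, "MEN2A-like") and in
the kinase domain (exon 16 codon 918, "MEN2B-like") produce different
clinical phenotypes, which raises two questions this pipeline is built to
answer on bulk expression data:

1. Do hereditary and sporadic MTCs differ globally in their transcriptome?
2. Does the *site* of the RET mutation (MEN2A-like vs MEN2B-like,
   pooling germline and somatic carriers) shape the expression profile?

The package implements the complete analysis chain for these questions —
probe filtering, unsupervised clustering, per-probe differential
expression, a cross-validated mutation-class classifier, and an RT-qPCR
validation stage — together with a synthetic-cohort generator so that
every stage can be exercised and tested without patient data.

## Pipeline stages and their models

### Probe filtering

Input is an RMA-summarized probe-set × sample matrix of log2 intensities.
Two filters run before any statistic:

* **Control probes** are removed by id prefix (default `"AFFX"`). The
  prefix list is configurable because control set naming is platform
  bookkeeping, not biology.
* **Low-variability probes**: a probe is kept only if at least
  `min_fraction` (default 15%) of samples deviate from the per-probe
  median by at least `fold_threshold` (default 1.5-fold) in either
  direction. On log2 data the deviation test is
  |x − median| ≥ log2(fold_threshold).

Two conventions had to be fixed because they are genuinely open:

* the median is the per-probe median of the log2 values (for an even
  number of samples, the midpoint of the two central values — identical to
  the median of linear intensities up to the monotone transform);
* the boundary is inclusive: a probe with *exactly* `min_fraction · n`
  deviating samples is retained, with no rounding of the product. A probe
  needing "fewer than 15%" to be discarded reads most literally this way.

Both choices are tested against a brute-force oracle that checks every
(probe, sample) pair on the linear scale.

### Unsupervised clustering

Samples are clustered with Ward minimum-variance linkage on Euclidean
distances between log2 profiles. We use the `ward.D2` convention (the
Lance–Williams update on squared distances with unsquared Euclidean
input), which is the variant most software means by "Ward on Euclidean
distance"; the method tag is configurable, and probes are not
standardized before clustering. Trees can be cut into k groups and
exported as Newick; a chi-square test between a 2-cluster cut and the
class labels quantifies "global separation". Merge heights are verified
against an independent Lance–Williams implementation on small cases.

### Differential expression

Per probe: Welch's unequal-variance t-test on log2 values, two-sided
(sidedness is not dictated by the design; two-sided is the standard for
expression screens), Benjamini–Hochberg FDR across probes, and a linear
fold change defined as the ratio of *linear-scale* group means
(mean of 2^x), numerator = first-listed contrast label. Group means on
the linear scale match how expression tables are conventionally printed
(values like 291.36 are linear intensities); tests stay on the log2 scale
where the noise is closer to Gaussian. Degenerate probes with zero
variance in both groups return p = 1 (equal means) rather than failing.

### Mutation-class classifier

The signature-building procedure couples univariate selection to a linear
support vector machine under leave-one-out cross-validation (LOOCV):

* In each fold the held-out sample is removed *first*; gene selection
  (Welch p < 0.001 AND fold change ≥ 4 or ≤ 0.25) runs on the training
  samples only. A test asserts that perturbing a held-out sample cannot
  change its own fold's gene set.
* Features enter the SVM as log2 intensities, standardized on
  training-fold means and standard deviations. C = 1, linear kernel; both
  configurable, neither tuned (no nested search).
* If no gene qualifies in a fold, the `fallback_k` (default 4) smallest-p
  genes are used and the fold is flagged. Real data with a genuine
  signature should never trigger this; it exists so the procedure is
  total.
* The reported metrics use the standard definitions (sensitivity =
  tp/(tp+fn), specificity = tn/(tn+fp), PPV, NPV) with the first-listed
  class as positive; zero-denominator ratios are reported as missing, not
  as 0. The final signature is re-selected on all samples with the same
  criteria and reported with its per-gene statistics.

### RT-qPCR validation

* **Standard curves**: ordinary least squares of Cq on log10(input
  quantity) per amplicon; amplification efficiency E = 10^(−1/slope) − 1,
  so perfect doubling gives slope −1/log10(2) ≈ −3.3219 and E = 1.
  Relative quantities invert the curve: q = 10^((Cq − intercept)/slope).
  Replicate Cq values are averaged per sample and gene *before*
  quantification (replicate handling is a free choice; averaging Cq is
  the common laboratory convention).
* **geNorm**: for reference gene j, stability M_j is the mean over the
  other references k of the SD across samples of log2(q_j/q_k);
  perfectly proportional references give M = 0. The per-sample
  normalization factor is the geometric mean of the reference quantities
  (defined up to a global scale, which cancels in fold changes). The
  stepwise exclusion of the least stable gene is implemented but optional
  because the validation design fixes three references (EIF3S10, HADHA,
  UBE2D2) a priori.
* **Group comparison**: normalized quantities are compared with a
  two-sided Mann–Whitney U test — the exact null distribution when both
  groups are small and untied, the tie-corrected normal approximation
  otherwise — and Bonferroni correction with family size equal to the
  number of genes in the validation run (9 by default, configurable).
  Fold change is the ratio of class means of normalized quantities
  (means rather than medians: a fixed, documented choice).

## The synthetic cohort generator

The generator exists so the pipeline is testable offline; its defaults
*are* the study conditions the package assumes.

* **Design sizes**: 21 MEN2A-like vs 9 MEN2B-like tumours for the
  mutation contrast; 22 hereditary vs 38 sporadic (19 somatic-RET,
  15 RET-negative, 4 unknown) for the background contrast, with two
  hereditary families of two samples each carried as annotation only;
  25 independent samples (16 vs 9) for qPCR validation.
* **Expression model**: probe-level log2 means ~
  Normal(`baseline_log2_mean` = 7, `baseline_log2_sd` = 2); i.i.d.
  Gaussian sample noise with `noise_log2_sd` = 0.5; planted probes shift
  the first contrast class additively by log2(FC), so the ratio of
  linear-scale class means equals the planted fold change in expectation.
  The within-group spread is an assumption, not a reported value: 0.5 on
  the log2 scale is typical of the across-tumour variability of
  RMA-summarized arrays and, conveniently, makes the 15%/1.5-fold
  variability filter genuinely selective (neither vacuous nor fatal).
* **Default planted signature**: the four mutation-class genes with their
  published fold changes (NTRK3 0.21, NNAT 6.54, GABRR1 0.18, PTPRT
  4.06), so a default simulation exercises the classifier end to end.
  The hereditary/sporadic contrast is simulated as null, matching the
  finding that this comparison shows no reproducible differences.
* **qPCR model**: the standard-curve model run forward — per-gene
  intercept, slope from the configured efficiency, per-sample cDNA input
  factor, Gaussian Cq noise (0.15 cycles). Reference genes vary only
  through the input factor, hence are exactly proportional across samples
  at zero noise (geNorm M = 0). NNAT (3.3×) and CDC14B (2.8×) are planted;
  the other seven targets are null.

What the generator does **not** emulate: probe–probe correlation,
within-family correlation, batch or array spatial effects, heavy-tailed
or intensity-dependent noise, and RET-negative biology (RAS-driven
tumours are annotation only). Passing tests therefore demonstrate that
the *procedures* are implemented correctly and behave as expected under a
clean Gaussian design — not that the biological conclusions would
replicate on real tumours.

## Numerical and testing choices

* Problem sizes in the test-suite simulations (probe counts of a few
  hundred to a few thousand, 5–50 seeds per property) were chosen as the
  smallest sizes at which each property is statistically decidable;
  statistical assertions use ~3σ bands around the expected value.
* The Mann–Whitney implementation is validated against exhaustive
  enumeration of all group assignments up to sizes (6, 6); BH against a
  brute-force step-up; the Welch statistic against `t.test`; Ward heights
  against a direct Lance–Williams recursion.
* One planted signature gene (PTPRT, fold change 4.06) sits essentially
  on the 4-fold selection boundary: its empirical fold change falls below
  4 in a substantial fraction of simulated cohorts at any realistic noise
  level, so tests require the three clear-margin genes always and the
  boundary gene only sometimes. This is a property of the published
  value, not of the implementation.
* Under a pure-noise cohort, LOOCV accuracy is *below* the majority-class
  rate (≈ 57% vs 70% at 21 vs 9; recomputed by the acceptance script).
  This is expected: the fallback always supplies maximally spurious
  training-separated genes, the SVM fits them, and a null held-out sample
  lands on either side of the boundary far more evenly than a
  majority-class guesser would. The permutation test asserts the
  scientifically meaningful direction — no better than majority — rather
  than equality with it.

## Known limitations

* No moderated variance estimation (limma-style shrinkage) — by design,
  the pipeline uses plain Welch tests; with 9 samples in the smaller
  class, very small groups make the per-probe variance noisy.
* Probe-to-gene mapping is the caller's responsibility: results are
  reported per probe set, with gene symbols carried only as labels.
* The qPCR stage quantifies via standard curves only; ΔΔCq is not
  implemented.
* The generator's independence assumptions make multiplicity behaviour
  (FDR, Bonferroni) slightly cleaner than on correlated real data.
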