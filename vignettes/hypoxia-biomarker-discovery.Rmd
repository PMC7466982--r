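---
title: "Temperature-robust hypoxia biomarker discovery and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-robust hypoxia biomarker discovery and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxpanel)
library(dplyr)
```

## The problem

Gill gene expression in juvenile salmonids responds to many stressors at
once, and the transcriptional response to low dissolved oxygen (DO) is
weak compared with the response to temperature. A biomarker panel meant to
flag *hypoxic* stress in the field is therefore only useful if its genes
respond to DO in the same direction at different temperatures, and do
*not* track temperature itself. `hypoxpanel` implements a full pipeline
for this problem: discovery of temperature-robust hypoxia-responsive genes
from a 2 x 2 DO-by-temperature RNA-seq experiment, transfer of the panel
to a qPCR platform, and validation of the panel's classification ability
on a larger multi-factor cohort. A synthetic-data module plants known
effects so that every stage can be scored against ground truth.

## Count model and discovery procedure

Counts are modelled as negative binomial, `var = mu + phi mu^2`, with
per-sample offsets `log(effective library size)`; effective library sizes
are raw library sizes times trimmed-mean-of-M (TMM) normalization factors.
The discovery stages are:

1. **Expression filter.** A gene is removed when its cpm is below a
   threshold in at least half the samples (rounded up). The threshold is
   recomputed from the data as `1e6 * 5 / min(library size)` — i.e. 5
   reads in the shallowest library, which is 0.4 cpm at a 12.5-million
   read minimum. Recomputing rather than hard-coding 0.4 keeps the rule
   meaningful at any depth. Whether the filter should use per-subset or
   global minimum depth is genuinely open; the global smallest library is
   used because it gives one threshold for the whole matrix.
2. **MDS screen.** Classical metric scaling of pairwise sample distances,
   each distance being the root-mean-square of that pair's top 500
   absolute log2-cpm differences (the leading-fold-change convention for
   count data). Each metadata factor's association with each axis (square
   root of the `lm` R², i.e. |point-biserial| for two-level factors) shows
   which factors dominate expression before any testing is done.
3. **Per-temperature contrasts.** The four treatment groups
   (normoxia/hypoxia x 10/18 degrees) are fitted with one NB mean each (a
   no-intercept four-group design). Dispersions are estimated per gene by
   maximizing the Cox-Reid adjusted profile likelihood on a 61-point
   log-spaced grid over [1e-4, 10], then shrunk toward the common
   dispersion on the log scale with prior weight `d0 = 10`:
   `phi_tilde = exp((d0 log phi0 + d_res log phi_hat) / (d0 + d_res))`.
   The hypoxia-vs-normoxia test within each temperature is a
   likelihood-ratio test (full: two group rates, reduced: one pooled
   rate) against chi-squared with 1 df at the shrunken dispersion. This
   deliberately trades exact replication of quasi-likelihood F-test
   machinery for a transparent likelihood-ratio formulation whose ranking
   and calibration behave the same way; the type-I rate on null
   simulations sits near 0.06 (checked by the test suite and the
   acceptance script). Fold changes are
   `log2((rate_1 + r0) / (rate_2 + r0))` with a prior rate `r0`
   equivalent to 0.5 reads at the average depth, so zero-count groups do
   not produce infinite estimates. Unadjusted p-values drive selection —
   at these sample sizes genuine hypoxia responses do not survive FDR
   control — and BH q-values are reported alongside.
4. **Direction-consistent intersection.** A gene survives if `p < 0.05`
   in *both* temperature contrasts and its fold changes share a nonzero
   sign. This is the temperature-robustness device: a gene whose DO
   response flips sign between temperatures (an interaction gene) is
   exactly what the panel must not contain.
5. **PCA ranking with confounder exclusion.** The surviving genes'
   log2-cpm profiles are centered and unit-scaled per gene and
   decomposed by SVD. Among the first five axes, the axis most
   correlated (point-biserial) with the DO label is the stressor axis
   and the distinct axis most correlated with temperature is the
   confounder axis; the stressor axis is oriented so hypoxia samples
   score positive (SVD signs are arbitrary; the convention makes
   downregulated genes come out with negative r). Genes correlated with
   the confounder axis at two-sided `p < 0.1` are excluded *before*
   ranking — exclusion-then-rank is one of two defensible readings and
   is the one implemented. The rest are ranked by the significance of
   their Pearson correlation with the stressor axis (ties by |r|, then
   gene id, for determinism), and the panel takes the top 20
   downregulated plus top 10 upregulated genes.

## qPCR quantification

Amplification efficiency comes from a serial-dilution standard curve:
ordinary least squares of Ct on log10(dilution), `E = 10^(-1/slope) - 1`,
so perfect doubling gives slope -3.32 and `E = 1`. The formula is the
standard signed form; the variant sometimes printed as
`(10^(1/slope) - 1) x 100` yields negative values under the conventional
negative slope, so the signed form is used and reported as a fraction.
Efficiency is reported but *not* used to correct quantification, which is
plain delta-delta-Ct: `dCt = Ct_assay - Ct_housekeeping` within sample,
`ddCt = dCt - dCt_calibrator` against the inter-array calibrator, and
log2 relative expression is `-ddCt` (one cycle = one log2 unit at 100%
efficiency). Ct values at or above 40 cycles are treated as missing —
non-amplification is not a measurement. Samples missing the housekeeping
Ct are dropped with a warning (there is nothing to normalize against);
missing target Cts propagate as missing expression. Reference-gene
choice is supported by a variance-decomposition stability value per
candidate: the mean over groups of `|delta_gk| + sqrt(sigma2_gk / n_k)`,
combining inter-group bias and intra-group noise; smaller is more stable.

## Panel validation

Within each stratum of the validation cohort (smolt stage x salinity for
live fish, salinity for distressed fish; strata with any class under 4
samples are skipped with the reason logged), samples are split
stratified 2/3 train / 1/3 test. On the training set a nearest shrunken
centroid (NSC) classifier soft-thresholds the standardized centroid
deviations `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` at a threshold
chosen by stratified internal cross-validation (grid of 30 thresholds
from 0 to max |d|; among CV-error minimizers the largest threshold wins,
i.e. the fewest genes). The class-size constant is
`m_k = sqrt(1/n_k - 1/n)` — the exact standard error factor for a class
centroid minus the overall centroid; the `sqrt(1/n_k + 1/n)` variant is
available as a switch. `s0` is the median of the pooled within-class
SDs. The NSC-selected genes then feed a two-class Fisher LDA with pooled
covariance regularized as `S + gamma I`, `gamma = 1e-6 trace(S)/p` by
default, and performance is reported on the untouched test third as a
confusion table, per-class accuracies, and their unweighted average.
Missing expression values are dropped from NSC scores; for the LDA they
are imputed with training-set gene means (the covariance has no natural
missing-data treatment at these panel sizes). Validation PCA figures are
fitted on training samples only and test samples are projected with the
training center/scale/loadings, so the figure cannot leak test
information. Cross-platform agreement is a Pearson correlation pooled
over gene-sample pairs plus per-gene correlations, with genes at
per-gene `p < 0.05` flagged concordant.

## What the generator emulates — and what it does not

`simulate_counts()` reproduces the discovery design: 2 temperatures x 2
DO levels, 6 fish per cell, NB counts with dispersion 0.1, library sizes
uniform on 9.4–16.9 million reads (the depth range of the motivating
experiment), and log-normal baseline abundances (sdlog 2.5) so a
realistic ~10% of genes fall under the cpm filter. Planted classes:
hypoxia-consistent up (2%) and down (3%) — down-weighted toward
downregulation as observed in gill hypoxia responses — temperature-only
(5%), interaction (2%, +effect at 10 degrees and -effect at 18, the
exact signature the intersection must reject), and null (88%), all with
|log2FC| = 2 additive on the log2 mean. `simulate_ct()` reproduces the
validation side: a 3-smolt-stage x 3-salinity x live/distressed cohort
with an inter-array calibrator, housekeeping Ct free of group effects,
one Ct per planted log2 unit (100% generation efficiency by design —
efficiency deviations are the estimator's job, not the generator's),
Gaussian technical noise of 0.25 cycles, 2% missing cells, and a global
expression upshift on half the panel in distressed fish, mimicking the
separation of moribund samples.

Real data differ in ways the generator does not attempt: no within-tank
correlation (the motivating design had replicate tanks, but no
within-tank correlation structure is published, so none is invented), no
gene-gene correlation, no mean-dependent dispersion trend, no batch or
lane effects, and no assay-specific amplification biases. Passing
recovery tests therefore demonstrates that the *procedure* is correct
and well-calibrated under its own model, not that any particular
biological panel is right.

## Numerical choices

* NB means are fitted by vectorized Fisher scoring on log rate
  (50-iteration cap, step clamp at ±5, convergence at 1e-10); all-zero
  groups get rate 0 and are flagged degenerate.
* The common dispersion is refined off-grid by golden-section search
  between the neighboring grid points: the 61-point grid's ~20% spacing
  is coarse enough to bias the shrinkage target and, through it, the
  type-I rate.
* LRT statistics are clamped at 0 (full model nests the reduced one;
  tiny negatives are numerical).
* PCA keeps singular values above `1e-10 x` the largest; constant genes
  are dropped with a warning everywhere a scale is needed.
* Deterministic tie-breaks throughout: correlation ranking by p, then
  |r|, then gene id; NSC prediction to the lexicographically first
  class; axis picking toward the lower index.
* All stochastic steps (simulation, splits, CV folds) take explicit
  seeds; identical seed and configuration give byte-identical outputs.

## Problem sizes used by the test suite

The suite exercises the full discovery pipeline at 5,000 genes x 24
samples over 20 replicate seeds, null calibration at 5,000 genes,
parameter-recovery checks at 600–2,000 genes, and oracle comparisons on
fixtures of at most 12 samples, where brute-force reimplementations of
the NSC, LDA, TMM, MDS and NB-likelihood formulas are feasible and
exact. `scripts/acceptance.R` re-runs the same computations from scratch
at those sizes and writes the measured quantities as JSON.

## Known limitations

* The DE stage is a likelihood-ratio approximation with empirically
  shrunken dispersions; it is mildly liberal (null rejection ~0.06 at
  nominal 0.05), which is acceptable for ranking-based discovery but
  should not be used for confirmatory inference.
* Only a single housekeeping assay is supported; geometric-mean
  multi-reference normalization is out of scope.
* Two-class validation only; the extreme-hypoxia four-group comparisons
  reduce to pairwise runs.
* The cpm filter and TMM assume bulk-like count depth; single-cell
  sparsity would need different defaults.
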