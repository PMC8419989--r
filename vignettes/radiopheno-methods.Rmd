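---
title: "Methods: radiomic phenotype selection and balanced random-forest diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic phenotype selection and balanced random-forest diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`radiopheno` implements a complete radiomics analysis for separating two
demyelinating diseases — multiple sclerosis (MS) and neuromyelitis optica
(NMO) — from brain-MRI white-matter lesion masks: feature extraction from
co-registered T2 and T1-MPRAGE volumes, multi-level feature selection that is
robust to a two-scanner (1.5T/3T) acquisition design, a balanced random
forest for diagnosis under class imbalance, exact Shapley-value
interpretation of individual predictions, and the summary-statistics
utilities used for clinical cohort tables. Because patient MRI cannot be
redistributed, the package ships a synthetic cohort generator that emulates
the study design; every stage is tested against it.

# The synthetic cohort generator

`synth_config()` / `generate_feature_cohort()` / `generate_volume_cohort()`
define the study conditions:

* **Design.** Two diagnosis classes crossed with two scanner strata. Default
  cell sizes are 38/30 (3T) and 40/8 (1.5T) for MS/NMO — the published cohort
  composition (116 subjects, 78 MS / 38 NMO).
* **Clinical covariates.** The source tables publish only means ± SD, so
  distribution families are our choice: age is Normal per class
  (36.5 ± 10.0 MS, 40.9 ± 11.7 NMO, floored at 18), EDSS is Normal
  (2.9 ± 1.5 / 3.8 ± 1.6) truncated to [0, 10] and rounded to the 0.5 grid,
  sex is Bernoulli with the published male rates (27/78 and 7/38), and
  disease duration is log-normal moment-matched to the published mean/SD
  (log-normal because duration is positive and right-skewed). The implied
  standardized EDSS class separation is about d = 0.58.
  `clinical_effect_size` can re-centre the NMO EDSS distribution at a chosen
  Cohen's d for experiments that need a calibrated clinical signal, and
  `clinical_null` removes all clinical class differences for null
  calibration.
* **Table mode** (default test path): features are standard normal with
  optional within-block equicorrelation (blocks of 10, correlation 0.3 by
  default — radiomic features are strongly grouped in practice). Planted
  class-informative features receive a ±d/2 class shift, so their population
  Cohen's d equals `effect_size`. Scanner-shifted features receive a
  ±`shift_size`/2 additive shift between strata (a location shift is what a
  rank-sum robustness filter detects; a multiplicative `scale_shift` is also
  available). Planted and shifted sets are disjoint so calibration tests stay
  clean. Feature names are drawn from the extraction registry so table-mode
  and image-mode cohorts are interchangeable downstream.
* **Image mode**: ellipsoidal lesions (1–3 per subject, semi-axes 2.5–5 mm by
  default; the source study does not describe lesion count/size
  distributions, so these are exposed in the configuration) inside an
  ellipsoidal brain envelope on a shared grid — alignment is generated, not
  registered. Class is encoded as the spatial autocorrelation length of the
  within-lesion intensity field (MS fine-grained, smoothing σ = 0.6 voxels;
  NMO coarse-grained, σ = 1.6), which is exactly the kind of signal texture
  matrices measure. Scanner is encoded as a global intensity gain (×1.2 at
  1.5T) and a noise-SD change (×1.5). Masks mark lesion voxels exactly.

What the generator does **not** emulate: MRI physics (bias fields, partial
volume, k-space noise correlation), anatomy, registration error, and the
heavy-tailed, highly collinear joint distribution of real radiomic features.
Passing tests therefore demonstrate algorithmic correctness and statistical
calibration under a controlled design, not clinical performance on patients.

# Feature extraction

Per sequence the extractor emits 1118 features: an 86-feature panel
(18 first-order + 22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM) on the original
image, on each of 4 Laplacian-of-Gaussian scales, and on each of 8 wavelet
subbands (86 × 13 = 1118; the published taxonomy prints the totals
18/68/344/688 and only the panel composition is our reconstruction with
standard family sizes). Names render as `H-<seq>-<filter>-<family>-<stat>`
with ids assigned by deterministic enumeration; printed ids from other
orderings are not promised to match.

Numerical conventions, all config-exposed:

* **Discretization**: fixed bin width (default 25 intensity units),
  min-referenced: `level = floor((v - min)/bw) + 1`. Adding a constant to the
  image leaves all discretized texture features unchanged.
* **GLCM**: distance 1, the 13 unique 3-D directions, symmetric matrices,
  features computed per direction then averaged; directions with no valid
  voxel pair are skipped. A VOI with no valid pair in any direction yields
  zeros with an `undefined` flag — downstream selection never sees missing
  values.
* **GLSZM** zones are 26-connected components of equal level; **GLRLM** runs
  are maximal same-level segments along each direction (averaged over
  directions); **GLDM** dependence counts 26-neighbours at Chebyshev
  distance 1 with level difference ≤ α (default 0), and the matrix column is
  `dependence + 1` so isolated voxels occupy column 1 and inverse-square
  terms stay defined.
* **LoG**: analytic kernel sampled at voxel centres per axis (anisotropic
  spacing respected), truncated at 5σ, second-derivative taps mean-corrected
  to sum to zero — constants map exactly to zero, ramps to zero away from the
  boundary (replicate padding). Scales σ ∈ {2, 3, 4, 5} mm, matching the
  `log2 … log5` naming; mm units are assumed as they are not stated in the
  source.
* **Wavelet**: decimated single-level separable transform with orthonormal
  Haar taps (exact Parseval identity on even dimensions; the source never
  names a kernel, and order-1 taps make tests exactly checkable). Subband
  letters follow array axis order; masks are block-OR downsampled to subband
  resolution.
* **First-order** moments use population (1/N) denominators; skewness and
  kurtosis of a constant sample are 0.

Standardization (`standardize()`) z-scores each feature against reference
(training) statistics; zero-SD columns map to 0 and are flagged. Rank-based
filters are unaffected by standardization; forests are only marginally
affected, so whether filtering precedes standardization is immaterial here —
the pipeline standardizes first for scale comparability.

# Multi-level feature selection

The pipeline is: scanner-robustness filter → class-relevance filter →
per-modality forward selection (T2, MPR, clinical) → fusion-level forward
selection.

* **Robustness filter** keeps a feature iff its scanner comparison is *not*
  significant (Wilcoxon rank-sum, two-sided, p ≥ α = 0.05) — the only
  direction consistent with "robust". The comparison runs within each
  diagnosis class and a feature is removed if either stratum is significant,
  because pooling classes would confound the class imbalance across scanners
  (38/30 vs 40/8); pooled testing is available via `by_class = FALSE`.
* **Relevance filter** keeps a feature iff the class comparison is
  significant (p < α). No multiple-testing correction is applied at either
  filter, matching the source procedure. The rank-sum test uses the exact
  null distribution for combined samples ≤ 12 without ties, otherwise the
  normal approximation with tie and continuity correction.
* **RF-SFS** (`rf_sfs()`): greedy forward selection scored by the
  cross-validated AUC of a balanced random forest (200 trees, stratified
  5-fold, 3 independent fold assignments averaged). Repeated CV is used
  because greedy selection takes an argmax over candidates each step and is
  therefore sensitive to scoring variance; averaging three fold assignments
  roughly halves the comparison noise at triple the cost. Ties break toward
  the earlier candidate (lower registry id), deterministically. The full AUC
  trace up to the cap is recorded and the returned phenotype is the prefix at
  the global trace maximum — the stopping point.
* **Caps** default to 10 per modality and 8 at fusion, bracketing the
  published final panel (3 T2 + 4 MPR + 1 clinical).

An important statistical caveat that the package's own acceptance tests
expose: the filters and the forward-selection scorer reuse the same training
table, so the trace values are optimistically biased. On pure-noise cohorts
(n = 120, 500 noise features) the α = 0.05 relevance filter passes the ~5%
most class-correlated noise features *of that sample*, and the greedy
maximization over them yields internal trace maxima well above chance —
an honest generalization estimate for a selected panel requires data not
touched by selection (the pipeline's independent test split provides this).
The planted-feature recovery experiments quantify what the selection can and
cannot distinguish at these sample sizes: informative features are recovered
reliably at the filtering and per-modality stages, while the fusion stage
occasionally trades a redundant planted feature for an overfit noise feature
whose apparent marginal gain is within scoring noise.

# Diagnostic model

`train_balanced_rf()` is a probability random forest (`ranger`) with
per-tree balanced class resampling: each tree sees an equal-count draw of
`floor(0.632 · m)` subjects per class *without* replacement, where m is the
minority count and 0.632 is the expected unique fraction of a same-size
bootstrap. An equal-count draw *with* replacement leaves the minority class
with fewer distinct points per tree, which measurably biases
probability-forest predictions against it; the without-replacement draw
keeps per-class support symmetric and makes predicted probabilities on
class-uninformative data centre on 0.5 across imbalance ratios — the
property the balanced design exists to provide. Class weights act on the
split criterion; since the in-bag sample is already balanced they default to
unit weights (inverse-frequency weights on top of a balanced resample would
re-tilt the criterion), and remain configurable.

Defaults: 500 trees, `ranger` default `√p` split candidates, probability
trees with default node size, threshold 0.5 for hard predictions, one
computation thread for bit-exact reproducibility. Positive class is NMO:
the published reviewer confusion matrix is integer-consistent only with NMO
positive (16/26 = 0.615 sensitivity, 45/60 = 0.750 specificity), and the
package adopts that orientation globally (configurable).

Evaluation: stratified 10-fold cross-validation (per-fold metrics at
threshold 0.5, averaged) and 1000-resample class-stratified bootstrap of the
independent test set (stratification preserves both classes in every
resample, so no resample needs redrawing). Dispersion is the sample SD
(denominator n−1) for both folds and resamples, with percentile 95%
intervals; the source never states its convention, and per-fold averaging at
threshold 0.5 is our documented reading of its cross-validated accuracy.
The stability statistic is `AUC_RSD = AUC_STD / AUC_MEAN`, which every
report satisfies identically by construction.

# Interpretation

`exact_shapley()` computes interventional (marginal) Shapley values by
exhaustive enumeration of all 2^M coalitions, with absent features
marginalized over a background table (the full training table by default).
For the ≤ 8-feature phenotypes in scope this is exact up to the background
average and avoids path-dependent tree approximations; the implementation
refuses M > 16. Local accuracy (`base + Σφ = prediction`) holds identically
because the empty and full coalitions are evaluated directly.
`permutation_shapley()` estimates the same quantity by sampling feature
orderings (over cached coalition values) and serves as an independent
convergence cross-check. Contribution percentages use the absolute-value
convention `100·|φᵢ|/Σ|φ|` — the only convention that yields positive
percentages for mixed-sign contributions. Model-level importance is the mean
|φ| across subjects; value-vs-contribution trends are ordinary
least-squares slopes with their sign. Explanations are computed on the
probability scale of the positive class (NMO).

# Clinical summary statistics

* `welch_t_from_summary()`: Welch's unequal-variance t from printed
  mean/SD/n, with Welch–Satterthwaite degrees of freedom. Welch is the
  default because it reproduces the published EDSS comparison (p = 0.005)
  from the printed summaries where the pooled Student variant gives 0.004;
  both are available. Recomputed age (0.051 vs printed 0.053) and duration
  (0.398 vs 0.396) differ in the third decimal, consistent with the authors
  testing unrounded raw data; this is documented, not chased.
* `yates_chi2()`: continuity-corrected χ², which reproduces the published
  sex comparison (p = 0.114; uncorrected gives ≈ 0.072), with the correction
  clipped at zero so proportional tables give χ² = 0 exactly.
* `infer_class_totals()` enumerates every integer class split consistent
  with a reported total, correct count and misdiagnosis counts, and returns
  the unique split whose sensitivity/specificity round to the printed
  values, checking both orientations.
* `feature_clinical_correlation()` defaults to Pearson with t-distribution
  p-values (Spearman available; the source names neither coefficient).

# Problem sizes and numerical tolerances

Exact identities (local accuracy, RSD, Parseval, round-trips) are asserted
at 1e-9 to 1e-12. Texture features are verified against brute-force
enumeration oracles on 100 random VOIs of at most 4 × 4 × 2 voxels at 1e-9.
Statistical calibration tests use the smallest sizes at which the assertion
is statistically stable: planted-effect calibration at 2000 subjects per
class (per-feature Cohen's-d standard error ≈ 0.03 against a ±0.15 band),
rank-sum null calibration at 2000 replicates, recovery experiments at the
study-scale n = 120 over 10 fixed seeds, and pipeline smoke tests on reduced
cohorts (40–60 subjects, tens of features) to keep the default suite fast.

# Known limitations

* Shape features, 2-D slice-wise extraction, resampling harmonization and
  gray-level normalization beyond binning are out of scope.
* The extractor is pure R; it is fast for lesion-scale VOIs (seconds per
  subject) but not optimized for whole-organ masks.
* Exact Shapley enumeration is limited to 16 features by design.
* Internal selection traces are optimistically biased (see above); only the
  independent-test bootstrap estimates generalization.
* The synthetic generator's independence and Gaussianity assumptions make
  planted signals easier to find than correlated real-world effects of equal
  size; recovery rates on real data would be lower.
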