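---
title: "Morphological connectivity and pain-threshold prediction: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological connectivity and pain-threshold prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: what is computed,
which choices were open and how they were settled, and what the verification
suite does and does not establish.

## From voxels to a connectivity network

The unit of raw data is the vector of gray-matter intensities of the voxels
inside one ROI of one participant's smoothed, modulated gray-matter map
(`ROISampleSet`). Segmentation, normalization, modulation and smoothing are
upstream of this package; it consumes their outputs, via NIfTI images plus a
labeled atlas (`extractROISamples()`) or a long-format table.

Each ROI's intensity distribution is estimated by a Gaussian-kernel KDE with
Scott's-rule bandwidth `h = sd(x) * n^(-1/5)` — the classical
single-dimension rule; only the bandwidth rule, not the kernel, is
prescribed by the approach being implemented, and the Gaussian kernel is the
standard companion. Morphological connectivity between two ROIs is the
symmetrized Kullback–Leibler divergence (J-divergence) of their two
densities. It is computed literally, with no similarity transform; an
`exp(-KL)` convention exists in parts of the morphometric-similarity
literature, but nothing in the source analysis indicates one was applied, so
raw J-divergence is the default and only shipped form.

Numerical choices, all of which were genuinely open:

* **Shared grid.** All of a participant's ROI densities are evaluated on one
  uniform 512-point grid spanning the pooled sample range of all ROIs plus 3
  mean bandwidths. A shared support makes all pairwise integrals mutually
  consistent and makes the 90 x 90 matrix exactly symmetric by
  construction; whether the original support was per-pair or global is
  unstated, and a global grid is the more defensible reading.
* **Density floor.** The KL integrand is undefined where a density is zero,
  so densities are floored and renormalized. The floor is *relative*
  (`1e-12` of each density's maximum) rather than absolute: KL divergence is
  invariant under affine reparameterization of the intensity axis, and an
  absolute floor silently breaks that invariance (a rescaling moves density
  values relative to a fixed threshold). With the relative floor,
  `buildMCMatrix()` is affine-invariant to machine precision, which the test
  suite asserts at `1e-3`.
* **Quadrature.** Trapezoid rule on the uniform grid; tolerances quoted in
  tests are calibrated at 512 points.

### Accuracy of the KDE/KL plug-in estimate

The synthetic generator makes every true divergence available in closed form
(two-Gaussian J-divergence), which exposes the estimator's behavior:

* For *mean-driven* divergences (similar spreads, different means) the
  plug-in estimate at 5000 voxels carries a small smoothing bias
  (≈ −h²/σ², about −3%) and a Monte-Carlo dispersion of roughly 5% per
  edge. Convergence checks therefore assert the cohort *median* relative
  error < 5% (plus a 20% per-edge cap) rather than a per-edge 5% bound,
  which single-edge sampling noise alone would violate.
* For *spread-driven* divergences (σ-contrast pairs) the KDE's fast tail
  decay under-covers the wider density's tails and biases the J-divergence
  upward, increasingly so for well-separated or strongly contrasting pairs.
  This is intrinsic to KDE-based KL, affects all participants of an edge
  almost equally (it is absorbed into the edge's mean level), and therefore
  has little effect on across-participant correlations — but absolute MC
  values for high-divergence edges should not be over-interpreted.

## The prediction model

Thresholds are fitted with PLSR, `y = X alpha + E`, computed by the SIMPLS
algorithm (de Jong's construction, implemented in RcppArmadillo) on
column-centered features and centered response. Features are **not**
variance-scaled by default: MC features share a scale, and the model as
written has no scaling step. A `standardize` flag exists for the GMV+MC
concatenation, which mixes scales. At `L = min(K, N-1)` components on
full-rank data SIMPLS reproduces the least-squares solution, and for a
single response it coincides with NIPALS-PLS1 — both facts are used as test
oracles. Each basis weight vector's sign is fixed (first non-negligible
entry positive) so per-fold coefficient vectors can be averaged.

The component count is chosen from the training coefficient of
determination: the cumulative R² over components (non-decreasing, since
SIMPLS scores are orthonormal) is computed once at `LMax`, and the default
rule takes the smallest L reaching R² ≥ 0.95; an elbow rule (smallest L
beyond which the next increment falls below 0.01) is also provided. The
wording of the source criterion is ambiguous about the exact cutoff and
about whether L was fixed globally or per fold; here both rules exist, the
component count is re-selected *within every training fold* (and for every
candidate feature subset), and `LMax` defaults to `min(10, K, N-2)`.

## Feature selection

Features are ranked by the absolute value of the (fold-averaged) PLSR
coefficients, ties broken by ascending index. The subset size is found by a
coarse-to-fine search: evaluate sizes `1, 1+s, 1+2s, …` (plus K) at the
first interval `s`, then re-search `best ± s` at the next finer interval.
The default ladder is (100, 10, 1), dropping intervals wider than K/4 — a
coarse stage that can only place 2–3 points cannot bracket an optimum — so a
4005-feature MC problem uses (100, 10, 1) and a 90-feature GMV problem
(10, 1), matching the reference procedure at both scales. Ties in the
minimal cross-validated error go to the smallest size. For unimodal
error-vs-size curves the coarse best provably lies within one coarse
interval of the optimum, so the fine stage recovers the exhaustive-search
answer; the tests assert this both for deterministic unimodal curves and for
a seeded cross-validated curve.

Two modes:

* `group_level` reproduces the reference procedure: one full leave-one-out
  pass with all features, average the per-fold coefficient vectors, rank
  once, and search with an evaluator that re-runs the full leave-one-out on
  each candidate subset. Because the subset is chosen using every
  participant's fold and the error is then reported on the same cohort,
  this estimate is optimistic.
* `nested` repeats ranking and search inside each training fold only and
  predicts the held-out participant with that fold's own subset — an honest
  cross-validated estimate. It reports per-fold subsets and their consensus
  (features kept in at least half the folds).

The search error metric defaults to MAE (the primary reported error of the
approach), configurable to MRAE or 1−r.

## Evaluation

Leave-one-participant-out cross-validation, MAE and MRAE per their
defining formulas, and Pearson's r between predicted and true values. MRAE
refuses zero true values rather than patching them with an epsilon — the
pain sensitivity score's min–max normalization puts one participant at
exactly 0, where relative error is undefined; reports carry `NA` there.
The pain sensitivity score itself is the arithmetic mean of the
min–max-normalized laser and cold thresholds (the stated 0–1 range pins the
normalization to min–max up to affine choice; a z-score variant is behind a
flag). Error sets of two models are compared with the two-sided Wilcoxon
rank-sum test (normal approximation with tie correction); correlation
differences use a participant bootstrap (B = 2000 default) because the
source analysis does not name its test — a Steiger-type dependent-correlation
z-test is available and both are labeled in the output. The MC–GMV
cross-feature correlation table uses Benjamini–Hochberg adjustment.

Lobe-pair summaries map each selected MC edge to the unordered pair of
hemisphere-specific lobes of its endpoints (16 groups: 8 lobes × 2
hemispheres). The packaged 90-ROI AAL-based parcellation ships with the
package's own coordinate-convention lobe assignment — the original
assignment table is not public — and is user-overridable via a CSV.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline was built for:
~221 participants and 90 ROIs at full scale, laser thresholds affinely
rescaled into 1.75–4.25 J, cold thresholds calibrated to 9.59 ± 0.38 s, and
thresholds driven by a sparse set of MC edges plus noise. Per-ROI intensity
distributions are Gaussian — a generator choice, not a claim about real
gray matter — so every edge's true divergence is closed-form. Participant
individuality enters through i.i.d. per-(participant, ROI) mean offsets
(SD `subjectSd`); planted thresholds are a weighted sum of
cohort-standardized true-MC features (weights default to alternating ±1,
since connections may raise or lower a threshold) plus Gaussian noise, with
the noise either given directly or derived from a target planted-model R²
(default 0.6, the magnitude of predictive accuracy such cohorts support).

What it does **not** emulate: voxel-level spatial autocorrelation, smoothing
kernels, registration error, non-Gaussian intensity distributions, or
covariate structure (age/sex). Passing tests on synthetic cohorts therefore
establish the *computational* correctness and statistical calibration of the
pipeline, not its field performance on real MRI.

One structural property of this generative model deserves emphasis. Regional
GMV is proportional to the ROI's mean intensity, so any threshold component
*linear* in the mean offsets leaks into GMV; conversely, forcing GMV to
carry none of the planted signal (equal ROI base means) makes every planted
true-MC feature a centered squared difference of offsets — a heavy-tailed,
χ²-like feature that is intrinsically harder to rank and recover at
moderate cohort sizes. The parameter-recovery suite uses the strict
GMV-null construction and reports what the method honestly achieves on it;
the recovery targets it is graded against were conceived for better-behaved
features, and the shortfall is a property of the generative model, not of
the estimator (the same pipeline recovers near-linear planted features at
r ≈ 0.65–0.85). The pure-noise calibration (nested mode centered on r = 0,
false-positive rates at nominal level) is unaffected by this.

## Problem sizes in the verification suite

The suite runs at desk scale by design: recovery cohorts of 60 participants
× 20 ROIs (190 MC features, 10 planted edges, planted R² 0.7, 500
voxels/ROI), null cohorts of 40 × 10, KDE consistency at 5000 voxels, and
oracle checks (OLS, NIPALS, exhaustive search) at N ≤ 120, K ≤ 50. Full
90-ROI cohorts are exercised for dimensional contracts and the packaged
parcellation.

## Known limitations

* KDE-KL tail bias for strongly σ-contrasting or well-separated ROI pairs
  (absolute values inflated; rankings across participants essentially
  preserved).
* Group-level selection is optimistic by construction; nested mode is the
  estimate to report for generalization claims.
* MRAE is undefined at zero targets and inflated near them (notably for the
  pain sensitivity score).
* The shipped lobe assignment is a reconstruction; analyses that hinge on
  precise lobe boundaries should supply their own table.
* Only SIMPLS ships as the regressor; the evaluation layer accepts any
  fit/predict pair, but no SVR or deep models are included.
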