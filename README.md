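# painMC

Individual pain sensitivity varies widely, and predicting it from brain
structure is of direct clinical interest. `painMC` implements an analysis
pipeline that predicts a person's pain thresholds from **morphological
connectivity (MC)** — the inter-regional similarity of gray-matter intensity
distributions in a structural MRI — and compares it against regional
gray-matter volume (GMV) features. It is aimed at researchers working with
smoothed, modulated gray-matter maps (VBM-style preprocessing) and
psychophysical pain thresholds.

## The model

For each participant and each ROI *r* of a 90-region cerebral parcellation
(AAL without the cerebellum), the voxel intensities inside the ROI are turned
into a density estimate *p_r(x)* by Gaussian kernel density estimation with
Scott's-rule bandwidth *h = σ̂ n^(−1/5)*. Each pair of ROIs is scored with
the symmetrized Kullback–Leibler divergence

KL(p, q) = ∫ ( p(x) log(p(x)/q(x)) + q(x) log(q(x)/p(x)) ) dx,

giving a symmetric 90 × 90 MC matrix per participant; its strictly lower
triangle (4005 features) is the connectivity feature vector. Thresholds are
modeled as

**y** = **X** α + **E**

and fitted with the SIMPLS partial least squares algorithm, the number of
latent components chosen from the coefficient of determination. Features are
ranked by |α| and the best subset size is found by a coarse-to-fine search
(intervals 100, 10, 1), all evaluated under leave-one-participant-out
cross-validation with MAE, MRAE and Pearson's r. Predictions can target the
laser pain threshold (J), the cold pain threshold (s), or their composite
min–max-normalized mean, the pain sensitivity score.

Two selection modes ship: `group_level` (rank fold-averaged coefficients
once for the whole cohort — the reference procedure, optimistic by
construction) and `nested` (selection repeated inside every training fold —
the unbiased estimate). Reports always name the mode.

Because suitable individual-level MRI cohorts are rarely shareable, the
package includes a synthetic cohort generator with Gaussian per-ROI
intensity distributions — so the true MC of every edge is available in
closed form — and thresholds planted as a sparse linear function of true MC
edges plus noise. Every stage of the pipeline is verifiable against this
ground truth.

## Worked example

```r
library(painMC)

spec <- cohortSpec(nParticipants = 60, nRois = 12, nVoxels = 300, seed = 42)
gen  <- generateCohort(spec)                     # samples + phenotypes + truth
se   <- buildCohortMC(gen$samples, phenotypes = gen$phenotypes)
X    <- mcFeatureMatrix(se)                      # 60 x 66 MC features
y    <- setNames(gen$phenotypes$laser_threshold_J,
                 gen$phenotypes$participant_id)

selG <- selectFeatures(X, y, mode = "group_level")
repG <- evaluatePrediction(predictions(selG), y,
                           featureSet = "mc", thresholdType = "laser",
                           mode = "group_level")
round(c(mStar = selG@mStar, MAE = repG$mae, MRAE = repG$mrae,
        r = repG$pearson_r), 3)
#>  mStar    MAE   MRAE      r
#> 13.000  0.352  0.129  0.652
```

The group-level search kept 13 of 66 MC features and predicts the held-out
laser thresholds with a mean absolute error of 0.35 J (13% relative error)
and a predicted-vs-true correlation of 0.65. The honest nested mode on the
same cohort is, as expected, slightly weaker:

```r
selN <- selectFeatures(X, y, mode = "nested")
repN <- evaluatePrediction(predictions(selN), y,
                           featureSet = "mc", thresholdType = "laser")
round(c(MAE = repN$mae, MRAE = repN$mrae, r = repN$pearson_r), 3)
#>   MAE  MRAE     r
#> 0.387 0.142 0.586
```

`lobePairCounts(selG, parcellation(gen$samples))` summarizes where the
selected connections concentrate, in the style of a lobe-pair table, and
`runPipeline()` / `runSweep()` orchestrate the full grid of 3 feature sets
(GMV, MC, GMV+MC) × 3 threshold types from a YAML config (see
`inst/scripts/painmc` for the command-line wrapper).

Real data enter through `extractROISamples()` (smoothed modulated GM NIfTI
images plus an integer-labeled atlas on the same grid) or
`readROISamplesTSV()` (long-format participant/ROI/value tables), with the
packaged 90-ROI parcellation from `defaultParcellation()` or your own CSV.

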