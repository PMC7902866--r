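#' @import methods
NULL

## The eight lobe labels used to group the 90 cerebral ROIs into 16
## hemisphere-specific lobes.
.LOBE_LEVELS <- c("prefrontal", "motorstrip", "insula", "parietal",
                  "temporal", "occipital", "limbic", "subcortical")

#' Brain parcellation
#'
#' An ordered table of regions of interest (ROIs). The row order is the
#' canonical feature order: GMV feature vectors and the rows/columns of every
#' morphological-connectivity (MC) matrix follow it, so it must be identical
#' across participants.
#'
#' @slot rois data.frame with columns `roi_id` (unique integer label, as in
#'   the atlas image), `name`, `hemisphere` (`"L"`/`"R"`) and `lobe` (one of
#'   prefrontal, motorstrip, insula, parietal, temporal, occipital, limbic,
#'   subcortical).
#' @export
setClass("Parcellation", representation(rois = "data.frame"))

setValidity("Parcellation", function(object) {
  df <- object@rois
  need <- c("roi_id", "name", "hemisphere", "lobe")
  if (!all(need %in% names(df)))
    return(paste("parcellation needs columns:", paste(need, collapse = ", ")))
  if (nrow(df) < 1) return("parcellation is empty")
  if (anyDuplicated(df$roi_id)) return("duplicate roi_id values")
  if (anyDuplicated(df$name)) return("duplicate ROI names")
  if (!all(df$hemisphere %in% c("L", "R")))
    return("hemisphere must be 'L' or 'R'")
  bad <- setdiff(unique(df$lobe), .LOBE_LEVELS)
  if (length(bad))
    return(paste0("unknown lobe name(s): ", paste(bad, collapse = ", "),
                  " (allowed: ", paste(.LOBE_LEVELS, collapse = ", "), ")"))
  TRUE
})

#' Per-participant, per-ROI gray-matter intensity samples
#'
#' Holds, for every participant and every ROI of a [Parcellation-class], the
#' vector of voxel-level gray-matter intensities (unitless modulated GM
#' probability times Jacobian). This is the raw material for regional GMV and
#' for the KDE densities that define morphological connectivity.
#'
#' @slot samples named list (one element per participant id) of named lists
#'   (one numeric vector per ROI name, in parcellation order).
#' @slot parcellation the [Parcellation-class] the samples are keyed to.
#' @export
setClass("ROISampleSet",
         representation(samples = "list", parcellation = "Parcellation"))

setValidity("ROISampleSet", function(object) {
  rn <- roiNames(object@parcellation)
  if (length(object@samples) < 1) return("no participants")
  if (is.null(names(object@samples)) || anyDuplicated(names(object@samples)))
    return("participant ids must be unique and named")
  for (pid in names(object@samples)) {
    s <- object@samples[[pid]]
    if (!identical(names(s), rn))
      return(sprintf("participant '%s': ROI cells must match parcellation order", pid))
    for (v in s) {
      if (!is.numeric(v) || length(v) < 1)
        return(sprintf("participant '%s': empty ROI sample vector", pid))
      if (!all(is.finite(v)))
        return(sprintf("participant '%s': non-finite intensities", pid))
    }
  }
  TRUE
})

#' Kernel density estimate of a regional intensity distribution
#'
#' Gaussian-kernel KDE with Scott's-rule bandwidth, evaluated on a uniform
#' grid, floored at a small positive constant and renormalized to unit
#' trapezoid integral so that the symmetrized KL divergence integrand is
#' always defined.
#'
#' @slot grid ordered evaluation points.
#' @slot density estimated density, strictly positive, trapezoid integral 1.
#' @slot bandwidth Scott's-rule kernel width.
#' @slot nSamples number of voxels the estimate was built from.
#' @slot samples the sample vector (kept so a pair of estimates can be
#'   re-evaluated on a common grid).
#' @export
setClass("DensityEstimate",
         representation(grid = "numeric", density = "numeric",
                        bandwidth = "numeric", nSamples = "integer",
                        samples = "numeric"))

setValidity("DensityEstimate", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid/density length mismatch")
  if (length(object@grid) < 8) return("grid too short")
  if (is.unsorted(object@grid, strictly = TRUE)) return("grid must be increasing")
  if (!all(is.finite(object@density)) || any(object@density <= 0))
    return("density must be finite and strictly positive (floored)")
  if (object@bandwidth <= 0) return("bandwidth must be > 0")
  if (abs(.trapz(object@grid, object@density) - 1) > 1e-3)
    return("density must integrate to 1 within 1e-3")
  TRUE
})

#' SIMPLS partial least squares regression model
#'
#' A centered SIMPLS fit of the linear model y = X alpha + E: `alpha` is the
#' coefficient vector on the original feature scale, the intercept is implied
#' by the stored centering constants, and the basis weight vectors and
#' response loadings are kept so the fit can be re-derived or truncated.
#'
#' @slot alpha coefficient vector, length K.
#' @slot intercept scalar intercept on the original scale.
#' @slot L number of latent components used.
#' @slot xMean,yMean centering constants.
#' @slot weights K x L SIMPLS basis (first non-negligible entry of each
#'   column positive, so fold-wise coefficient vectors average meaningfully).
#' @slot q length-L response loadings.
#' @slot r2 cumulative training R^2 for component counts 1..L.
#' @slot featureNames feature labels in training column order.
#' @export
setClass("PLSRModel",
         representation(alpha = "numeric", intercept = "numeric", L = "integer",
                        xMean = "numeric", yMean = "numeric",
                        weights = "matrix", q = "numeric", r2 = "numeric",
                        featureNames = "character"))

setValidity("PLSRModel", function(object) {
  K <- length(object@alpha)
  if (!all(is.finite(object@alpha))) return("alpha must be finite")
  if (length(object@xMean) != K) return("xMean length != K")
  if (length(object@featureNames) != K) return("featureNames length != K")
  if (object@L < 1) return("L must be >= 1")
  TRUE
})

#' Result of coefficient-ranked feature selection
#'
#' @slot indices indices (into the training feature order) of the selected
#'   subset, i.e. the top-`mStar` of the coefficient ranking.
#' @slot names feature labels of the selected subset.
#' @slot mStar chosen subset size.
#' @slot trace data.frame of the coarse-to-fine search: columns `stage`
#'   (search interval), `m`, `error`.
#' @slot mode `"group_level"` (fold-averaged coefficients, the evaluator
#'   re-runs a full leave-one-out pass per candidate size) or `"nested"`
#'   (selection repeated inside every training fold).
#' @slot ranking full feature ranking the subset was cut from.
#' @slot avgAlpha the averaged coefficient vector behind the ranking.
#' @slot perFold nested mode only: list of per-fold selected index vectors.
#' @slot consensus nested mode only: features selected in >= 50% of folds.
#' @slot pred leave-one-out predictions of the selected model (named by
#'   participant).
#' @export
setClass("SelectionResult",
         representation(indices = "integer", names = "character",
                        mStar = "integer", trace = "data.frame",
                        mode = "character", ranking = "integer",
                        avgAlpha = "numeric", perFold = "list",
                        consensus = "integer", pred = "numeric"))

setValidity("SelectionResult", function(object) {
  if (!object@mode %in% c("group_level", "nested"))
    return("mode must be 'group_level' or 'nested'")
  if (length(object@indices) != object@mStar)
    return("number of selected features must equal mStar")
  if (object@mode == "group_level") {
    if (!identical(object@indices, object@ranking[seq_len(object@mStar)]))
      return("selected set must be the top-mStar of the ranking")
    if (nrow(object@trace)) {
      best <- min(object@trace$error)
      em <- object@trace$m[object@trace$error <= best]
      if (!object@mStar %in% em)
        return("mStar must attain the minimal traced error")
    }
  }
  TRUE
})

#' Specification of a synthetic cohort
#'
#' Defines a cohort whose per-ROI intensity distributions are Gaussian (so
#' the true symmetrized KL divergence of every ROI pair is available in
#' closed form) and whose pain thresholds are planted as a sparse linear
#' function of the true MC edges plus noise. See [generateCohort()].
#'
#' @export
setClass("CohortSpec",
         representation(nParticipants = "integer", nRois = "integer",
                        nVoxels = "integer", roiMeanBase = "numeric",
                        subjectSd = "numeric", roiSigmaBase = "numeric",
                        plantedEdges = "matrix", plantedWeights = "numeric",
                        plantedEdgesCold = "matrix", plantedWeightsCold = "numeric",
                        noiseSd = "numeric", plantedR2 = "numeric",
                        laserRange = "numeric", coldMeanSd = "numeric",
                        seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nRois < 3) return("nRois must be >= 3")
  if (object@nParticipants < 3) return("nParticipants must be >= 3")
  if (object@nVoxels < 2) return("nVoxels must be >= 2")
  if (length(object@roiMeanBase) != object@nRois) return("roiMeanBase length != nRois")
  if (length(object@roiSigmaBase) != object@nRois) return("roiSigmaBase length != nRois")
  if (any(object@roiSigmaBase <= 0)) return("roiSigmaBase must be > 0")
  if (object@subjectSd < 0) return("subjectSd must be >= 0")
  chk <- .checkEdges(object@plantedEdges, object@nRois)
  if (!isTRUE(chk)) return(chk)
  if (nrow(object@plantedEdges) != length(object@plantedWeights))
    return("plantedWeights length must match plantedEdges rows")
  if (nrow(object@plantedEdgesCold)) {
    chk <- .checkEdges(object@plantedEdgesCold, object@nRois)
    if (!isTRUE(chk)) return(chk)
    if (nrow(object@plantedEdgesCold) != length(object@plantedWeightsCold))
      return("plantedWeightsCold length must match plantedEdgesCold rows")
  }
  if (any(object@noiseSd < 0)) return("noiseSd must be >= 0")
  if (length(object@laserRange) != 2 || object@laserRange[1] >= object@laserRange[2])
    return("laserRange must be (min, max) with min < max")
  if (length(object@coldMeanSd) != 2 || object@coldMeanSd[2] <= 0)
    return("coldMeanSd must be (mean, sd) with sd > 0")
  TRUE
})

.checkEdges <- function(edges, nRois) {
  if (!is.matrix(edges) || ncol(edges) != 2)
    return("planted edges must be a 2-column matrix of ROI indices")
  if (nrow(edges) < 1) return("at least one planted edge is required")
  if (any(edges < 1) || any(edges > nRois))
    return("planted edge references a missing ROI")
  if (any(edges[, 1] == edges[, 2])) return("planted edges must join distinct ROIs")
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) return("planted edges must be distinct unordered pairs")
  TRUE
}
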