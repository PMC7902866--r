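#' Closed-form symmetrized KL divergence of two Gaussians
#'
#' For p = N(mu1, sd1^2) and q = N(mu2, sd2^2),
#' KL(p||q) + KL(q||p) =
#' (sd1^2 + d^2) / (2 sd2^2) + (sd2^2 + d^2) / (2 sd1^2) - 1, d = mu1 - mu2.
#' This is the analytic ground truth the KDE/quadrature pipeline is checked
#' against on synthetic cohorts.
#'
#' @param mu1,sd1,mu2,sd2 parameters of the two Gaussians (vectorized;
#'   standard deviations must be > 0)
#' @return divergence (>= 0; 0 iff the parameter pairs are identical)
#' @export
gaussianSymmetricKL <- function(mu1, sd1, mu2, sd2) {
  if (any(!is.finite(sd1)) || any(!is.finite(sd2)) ||
      any(sd1 <= 0) || any(sd2 <= 0))
    stop("standard deviations must be finite and > 0")
  d2 <- (mu1 - mu2)^2
  (sd1^2 + d2) / (2 * sd2^2) + (sd2^2 + d2) / (2 * sd1^2) - 1
}

#' Specify a synthetic cohort
#'
#' Defaults emulate the target study population: 221 participants, 90
#' cerebral ROIs, laser thresholds rescaled into 1.75-4.25 J and cold
#' thresholds calibrated to 9.59 +/- 0.38 s, with thresholds driven by a
#' sparse set of MC edges plus noise (planted linear model R^2 = 0.6 by
#' default, matching the magnitude of prediction accuracy such cohorts
#' support). Per-ROI intensity distributions are Gaussian so true MC is
#' available in closed form.
#'
#' @param nParticipants,nRois,nVoxels cohort dimensions (voxels per ROI)
#' @param roiMeanBase per-ROI baseline mean intensity (scalar recycled)
#' @param subjectSd SD of independent participant-level ROI mean offsets
#' @param roiSigmaBase per-ROI intensity SD (scalar recycled)
#' @param plantedEdges 2-column matrix of ROI index pairs carrying signal
#'   (default: the first `min(20, choose(nRois,2))` lower-triangle pairs
#'   spread over distinct ROIs)
#' @param plantedWeights weight per planted edge, applied to the
#'   cohort-standardized true-MC feature (default: alternating +1/-1, since
#'   connections may raise or lower a threshold)
#' @param plantedEdgesCold,plantedWeightsCold optional cold-specific plant
#'   (default: shared with laser)
#' @param noiseSd length-2 threshold-noise SD (laser, cold), on the scale of
#'   the standardized planted predictor; ignored when `plantedR2` is set
#' @param plantedR2 target R^2 of the planted linear model; the noise SD is
#'   derived from the realized predictor variance (set `NA` to use `noiseSd`)
#' @param laserRange (min, max) laser threshold in J; generated thresholds
#'   are affinely rescaled into this range
#' @param coldMeanSd (mean, sd) of cold thresholds in s
#' @param seed integer RNG seed; identical specs reproduce bit-identical
#'   cohorts
#' @return a [CohortSpec-class]
#' @export
cohortSpec <- function(nParticipants = 221, nRois = 90, nVoxels = 500,
                       roiMeanBase = seq(0.35, 0.75, length.out = nRois),
                       subjectSd = 0.03,
                       roiSigmaBase = seq(0.07, 0.13, length.out = nRois),
                       plantedEdges = NULL, plantedWeights = NULL,
                       plantedEdgesCold = NULL, plantedWeightsCold = NULL,
                       noiseSd = c(laser = 1, cold = 1), plantedR2 = 0.6,
                       laserRange = c(1.75, 4.25),
                       coldMeanSd = c(9.59, 0.38), seed = 1L) {
  nRois <- as.integer(nRois)
  if (is.null(plantedEdges)) {
    k <- min(20L, floor(nRois / 2))
    plantedEdges <- cbind(seq(1L, by = 2L, length.out = k),
                          seq(2L, by = 2L, length.out = k))
  }
  plantedEdges <- matrix(as.integer(plantedEdges), ncol = 2)
  if (is.null(plantedWeights))
    plantedWeights <- rep_len(c(1, -1), nrow(plantedEdges))
  if (is.null(plantedEdgesCold)) {
    plantedEdgesCold <- matrix(integer(0), 0, 2)
    plantedWeightsCold <- numeric(0)
  } else {
    plantedEdgesCold <- matrix(as.integer(plantedEdgesCold), ncol = 2)
    if (is.null(plantedWeightsCold))
      plantedWeightsCold <- rep(1, nrow(plantedEdgesCold))
  }
  noiseSd <- rep_len(as.numeric(noiseSd), 2)
  new("CohortSpec",
      nParticipants = as.integer(nParticipants), nRois = nRois,
      nVoxels = as.integer(nVoxels),
      roiMeanBase = rep_len(as.numeric(roiMeanBase), nRois),
      subjectSd = as.numeric(subjectSd),
      roiSigmaBase = rep_len(as.numeric(roiSigmaBase), nRois),
      plantedEdges = plantedEdges,
      plantedWeights = as.numeric(plantedWeights),
      plantedEdgesCold = plantedEdgesCold,
      plantedWeightsCold = as.numeric(plantedWeightsCold),
      noiseSd = noiseSd, plantedR2 = as.numeric(plantedR2),
      laserRange = as.numeric(laserRange),
      coldMeanSd = as.numeric(coldMeanSd), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nParticipants, "participants x", object@nRois,
      "ROIs,", object@nVoxels, "voxels/ROI,",
      nrow(object@plantedEdges), "planted edges, seed", object@seed, "\n")
})

## Map a 2-column edge matrix to positions in the row-major lower-triangle
## feature order.
.edgeToFeatureIndex <- function(edges, nRois) {
  ij <- .lowerPairs(nRois)
  key <- paste(ij[, 1], ij[, 2])
  m <- match(paste(pmax(edges[, 1], edges[, 2]),
                   pmin(edges[, 1], edges[, 2])), key)
  if (anyNA(m)) stop("planted edge references a missing ROI pair")
  m
}

#' Generate a synthetic cohort with closed-form ground truth
#'
#' Per participant i and ROI r, voxel intensities are drawn from
#' N(mu_ir, sigma_r^2) with mu_ir = roiMeanBase_r + offset_ir (offsets i.i.d.
#' N(0, subjectSd^2)). The true MC of every ROI pair is the closed-form
#' Gaussian symmetrized KL of the participant's (mu, sigma) parameters.
#' Pain thresholds are planted on the cohort-standardized true-MC features of
#' the planted edges: the laser threshold is the noisy linear predictor
#' min-max rescaled into `laserRange`; the cold threshold is the (optionally
#' cold-specific) predictor standardized to `coldMeanSd`.
#'
#' @param spec a [CohortSpec-class]
#' @param parc optional [Parcellation-class] with `nRois` rows (default: a
#'   [syntheticParcellation()])
#' @return list with elements `samples` ([ROISampleSet-class]),
#'   `phenotypes` (data.frame: participant_id, laser_threshold_J,
#'   cold_threshold_s), and `truth` (list: `trueMC` participants x pairs
#'   matrix, `mu`, `sigma`, planted edges/weights and feature indices,
#'   realized noise, linear predictors)
#' @export
generateCohort <- function(spec, parc = NULL) {
  validObject(spec)
  if (is.null(parc)) parc <- syntheticParcellation(spec@nRois)
  if (nRois(parc) != spec@nRois) stop("parcellation size != spec nRois")
  .withSeed(spec@seed, {
    nP <- spec@nParticipants; nR <- spec@nRois
    ids <- sprintf("sub-%03d", seq_len(nP))
    mu <- matrix(stats::rnorm(nP * nR, 0, spec@subjectSd), nP, nR)
    mu <- sweep(mu, 2, spec@roiMeanBase, "+")
    sigma <- spec@roiSigmaBase
    ij <- .lowerPairs(nR)
    trueMC <- matrix(NA_real_, nP, nrow(ij),
                     dimnames = list(ids, mcFeatureNames(parc)))
    for (k in seq_len(nrow(ij)))
      trueMC[, k] <- gaussianSymmetricKL(mu[, ij[k, 1]], sigma[ij[k, 1]],
                                         mu[, ij[k, 2]], sigma[ij[k, 2]])
    rn <- roiNames(parc)
    samples <- lapply(seq_len(nP), function(i) {
      s <- lapply(seq_len(nR), function(r)
        stats::rnorm(spec@nVoxels, mu[i, r], sigma[r]))
      names(s) <- rn
      s
    })
    names(samples) <- ids
    sset <- ROISampleSet(samples, parc)

    plant <- function(edges, weights, noiseSd) {
      fi <- .edgeToFeatureIndex(edges, nR)
      Z <- scale(trueMC[, fi, drop = FALSE])
      lin <- as.numeric(Z %*% weights)
      if (is.finite(spec@plantedR2)) {
        r2 <- spec@plantedR2
        noiseSd <- if (r2 >= 1) 0 else stats::sd(lin) * sqrt((1 - r2) / r2)
      }
      eps <- stats::rnorm(nP, 0, noiseSd)
      list(idx = fi, lin = lin, eps = eps, raw = lin + eps)
    }
    laserP <- plant(spec@plantedEdges, spec@plantedWeights, spec@noiseSd[1])
    coldP <- if (nrow(spec@plantedEdgesCold))
      plant(spec@plantedEdgesCold, spec@plantedWeightsCold, spec@noiseSd[2])
    else plant(spec@plantedEdges, spec@plantedWeights, spec@noiseSd[2])

    laser <- spec@laserRange[1] +
      .minmax(laserP$raw) * diff(spec@laserRange)
    zc <- (coldP$raw - mean(coldP$raw)) / stats::sd(coldP$raw)
    cold <- spec@coldMeanSd[1] + spec@coldMeanSd[2] * zc

    phenotypes <- data.frame(participant_id = ids,
                             laser_threshold_J = laser,
                             cold_threshold_s = cold,
                             stringsAsFactors = FALSE)
    truth <- list(trueMC = trueMC, mu = mu, sigma = sigma,
                  plantedEdges = spec@plantedEdges,
                  plantedWeights = spec@plantedWeights,
                  plantedFeatureIdx = laserP$idx,
                  plantedFeatureIdxCold = coldP$idx,
                  linPredLaser = laserP$lin, linPredCold = coldP$lin,
                  noiseLaser = laserP$eps, noiseCold = coldP$eps)
    list(samples = sset, phenotypes = phenotypes, truth = truth)
  })
}
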