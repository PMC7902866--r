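## Strictly-lower-triangle (row-major) pair indices of an n x n matrix:
## (2,1), (3,1), (3,2), (4,1), ...
.lowerPairs <- function(n) {
  i <- rep(2:n, times = 1:(n - 1))
  j <- unlist(lapply(2:n, function(k) seq_len(k - 1)))
  cbind(i = i, j = j)
}

#' ROI-pair feature names of a parcellation
#'
#' Names of the n(n-1)/2 strictly-lower-triangle MC features, row-major, as
#' `"ROI_i-ROI_j"` with i after j in parcellation order.
#'
#' @param parc a [Parcellation-class]
#' @return character vector of length nRois*(nRois-1)/2
#' @export
mcFeatureNames <- function(parc) {
  rn <- roiNames(parc)
  ij <- .lowerPairs(length(rn))
  paste0(rn[ij[, 1]], "-", rn[ij[, 2]])
}

#' Morphological connectivity matrix of one participant
#'
#' Estimates a Gaussian KDE (Scott's-rule bandwidth) for every ROI of the
#' participant on one shared uniform grid spanning the pooled sample range of
#' all ROIs padded by 3 mean bandwidths, then fills the ROI x ROI matrix with
#' the symmetrized KL divergence of each density pair (trapezoid quadrature).
#' A shared grid keeps every pairwise integral on the same support.
#'
#' @param samples a [ROISampleSet-class]
#' @param participant participant id
#' @param nGrid grid points (default 512; quadrature tolerances quoted in the
#'   package documentation are calibrated at this size)
#' @param pad grid padding in pooled (mean) bandwidths
#' @return symmetric nRois x nRois matrix, zero diagonal, dimnames = ROI names
#' @export
buildMCMatrix <- function(samples, participant, nGrid = 512, pad = 3) {
  s <- roiSamples(samples, participant)
  rn <- names(s)
  sds <- vapply(s, stats::sd, numeric(1))
  if (any(!is.finite(sds) | sds <= 0))
    stop("degenerate (constant) ROI sample for participant ", participant,
         ": ", paste(rn[!is.finite(sds) | sds <= 0], collapse = ", "))
  h <- vapply(s, scottBandwidth, numeric(1))
  lo <- min(vapply(s, min, numeric(1))) - pad * mean(h)
  hi <- max(vapply(s, max, numeric(1))) + pad * mean(h)
  grid <- seq(lo, hi, length.out = nGrid)
  P <- t(vapply(seq_along(s), function(r) {
    d <- .floorDensity(.kdeOnGrid(s[[r]], grid, h[r]))
    d / .trapz(grid, d)
  }, numeric(nGrid)))
  dx <- grid[2] - grid[1]
  w <- rep(dx, nGrid); w[c(1, nGrid)] <- dx / 2
  Lg <- log(P)
  M <- P %*% t(Lg * rep(w, each = nrow(P)))  # M[i,j] = integral p_i log p_j
  D <- diag(M) - M                           # KL(p_i || p_j)
  skl <- D + t(D)
  skl <- pmax(skl, 0)
  diag(skl) <- 0
  dimnames(skl) <- list(rn, rn)
  skl
}

#' Vectorize the strictly lower triangle of an MC matrix
#'
#' @param mc symmetric matrix with zero diagonal (ROI dimnames)
#' @param tol symmetry tolerance; larger asymmetry is an error
#' @return named vector of length n(n-1)/2, row-major strictly-lower-triangle
#'   order, with the ROI name vector attached as attribute `"rois"`
#' @export
vectorizeLowerTriangle <- function(mc, tol = 1e-8) {
  if (!is.matrix(mc) || nrow(mc) != ncol(mc)) stop("mc must be square")
  if (max(abs(mc - t(mc))) > tol)
    stop("matrix is asymmetric beyond tolerance ", tol)
  n <- nrow(mc)
  ij <- .lowerPairs(n)
  v <- mc[ij]
  rn <- rownames(mc)
  if (is.null(rn)) rn <- paste0("ROI", seq_len(n))
  names(v) <- paste0(rn[ij[, 1]], "-", rn[ij[, 2]])
  attr(v, "rois") <- rn
  v
}

#' Rebuild the symmetric matrix from a lower-triangle feature vector
#'
#' @param v vector from [vectorizeLowerTriangle()] (attribute `"rois"` kept)
#' @return symmetric matrix with zero diagonal
#' @export
matrixFromLowerTriangle <- function(v) {
  rn <- attr(v, "rois")
  n <- if (!is.null(rn)) length(rn) else (1 + sqrt(1 + 8 * length(v))) / 2
  n <- as.integer(round(n))
  if (n * (n - 1) / 2 != length(v)) stop("vector length is not n(n-1)/2")
  m <- matrix(0, n, n)
  ij <- .lowerPairs(n)
  m[ij] <- v
  m <- m + t(m)
  if (!is.null(rn)) dimnames(m) <- list(rn, rn)
  m
}

#' Cohort-wide MC feature table
#'
#' Builds each participant's MC matrix ([buildMCMatrix()]) and assembles the
#' lower-triangle feature vectors into a `SummarizedExperiment`: assay
#' `"mc"` is features x participants, `rowData` carries the ROI pair of each
#' feature, and `colData` carries the phenotypes when supplied.
#'
#' @param samples a [ROISampleSet-class]
#' @param phenotypes optional data.frame with a `participant_id` column
#' @param nGrid,pad forwarded to [buildMCMatrix()]
#' @return a [SummarizedExperiment::SummarizedExperiment-class]
#' @export
buildCohortMC <- function(samples, phenotypes = NULL, nGrid = 512, pad = 3) {
  ids <- participants(samples)
  parc <- parcellation(samples)
  fn <- mcFeatureNames(parc)
  mat <- matrix(NA_real_, length(fn), length(ids), dimnames = list(fn, ids))
  for (pid in ids)
    mat[, pid] <- vectorizeLowerTriangle(
      buildMCMatrix(samples, pid, nGrid = nGrid, pad = pad))
  rn <- roiNames(parc)
  ij <- .lowerPairs(length(rn))
  rd <- S4Vectors::DataFrame(roi_a = rn[ij[, 1]], roi_b = rn[ij[, 2]],
                             idx_a = ij[, 1], idx_b = ij[, 2])
  cd <- S4Vectors::DataFrame(participant_id = ids, row.names = ids)
  if (!is.null(phenotypes)) {
    m <- match(ids, as.character(phenotypes$participant_id))
    if (anyNA(m)) stop("phenotypes missing participants: ",
                       paste(ids[is.na(m)], collapse = ", "))
    for (cn in setdiff(names(phenotypes), "participant_id"))
      cd[[cn]] <- phenotypes[[cn]][m]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(mc = mat), rowData = rd, colData = cd,
    metadata = list(nGrid = nGrid, pad = pad))
}

#' Participants x features matrix from a cohort MC experiment
#' @param se the `SummarizedExperiment` from [buildCohortMC()]
#' @export
mcFeatureMatrix <- function(se) t(SummarizedExperiment::assay(se, "mc"))

#' Write an MC matrix as square CSV / edge-list TSV
#'
#' @param mc matrix from [buildMCMatrix()]
#' @param path output file
#' @export
writeMCMatrixCSV <- function(mc, path) {
  utils::write.csv(as.data.frame(mc), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeMCMatrixCSV
#' @export
writeEdgeListTSV <- function(mc, path) {
  v <- vectorizeLowerTriangle(mc)
  rn <- attr(v, "rois")
  ij <- .lowerPairs(length(rn))
  utils::write.table(
    data.frame(roi_a = rn[ij[, 1]], roi_b = rn[ij[, 2]], value = as.numeric(v)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
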