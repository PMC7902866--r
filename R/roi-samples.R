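#' Construct a ROISampleSet
#'
#' @param samples named list (participant id) of named lists (ROI name ->
#'   numeric vector of voxel intensities), ROI names in parcellation order.
#' @param parcellation a [Parcellation-class]
#' @return a [ROISampleSet-class]
#' @export
ROISampleSet <- function(samples, parcellation) {
  new("ROISampleSet", samples = samples, parcellation = parcellation)
}

#' @describeIn ROISampleSet participant ids (always in sorted order, so the
#'   set is invariant to input file ordering)
#' @param x a ROISampleSet
#' @export
setMethod("participants", "ROISampleSet", function(x) names(x@samples))

#' @describeIn ROISampleSet number of ROIs
#' @export
setMethod("nRois", "ROISampleSet", function(x) nRois(x@parcellation))

#' @describeIn ROISampleSet ROI names
#' @export
setMethod("roiNames", "ROISampleSet", function(x) roiNames(x@parcellation))

#' @describeIn ROISampleSet the intensity vector of one cell, or the named
#'   list of all ROI vectors of a participant when `roi` is missing
#' @param participant participant id
#' @param roi ROI name
#' @export
setMethod("roiSamples", "ROISampleSet", function(x, participant, roi) {
  if (!participant %in% names(x@samples))
    stop("unknown participant: ", participant)
  if (missing(roi)) return(x@samples[[participant]])
  v <- x@samples[[participant]][[roi]]
  if (is.null(v)) stop("unknown ROI: ", roi)
  v
})

#' Parcellation of a sample set
#' @param x a [ROISampleSet-class]
#' @export
parcellation <- function(x) x@parcellation

setMethod("show", "ROISampleSet", function(object) {
  cat("ROISampleSet:", length(object@samples), "participants x",
      nRois(object), "ROIs\n")
  nv <- lengths(object@samples[[1]])
  cat("  voxels per ROI (participant 1):", min(nv), "-", max(nv), "\n")
})

#' Build a ROISampleSet from a long-format table
#'
#' @param df data.frame with columns `participant_id`, `roi_id`, `value`
#' @param parc a [Parcellation-class]; every (participant, roi_id) cell must
#'   be present for all of its ROIs
#' @param minVoxels minimum voxels per cell (density estimation is unreliable
#'   below ~10)
#' @return a [ROISampleSet-class]
#' @export
roiSampleSetFromLong <- function(df, parc, minVoxels = 10) {
  need <- c("participant_id", "roi_id", "value")
  if (!all(need %in% names(df)))
    stop("long table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$value))) stop("non-finite intensity values in table")
  ids <- sort(unique(as.character(df$participant_id)))
  rt <- roiTable(parc)
  byP <- split(df, as.character(df$participant_id))
  samples <- lapply(ids, function(pid) {
    d <- byP[[pid]]
    byR <- split(d$value, d$roi_id)
    out <- vector("list", nrow(rt))
    names(out) <- rt$name
    for (i in seq_len(nrow(rt))) {
      v <- byR[[as.character(rt$roi_id[i])]]
      if (is.null(v))
        stop("participant ", pid, ": missing ROI ", rt$name[i],
             " (roi_id ", rt$roi_id[i], ")")
      if (length(v) < minVoxels)
        stop("participant ", pid, ": ROI ", rt$name[i], " has ", length(v),
             " voxels (< minVoxels = ", minVoxels, ")")
      out[[i]] <- as.numeric(v)
    }
    out
  })
  names(samples) <- ids
  ROISampleSet(samples, parc)
}

#' Write / read a ROISampleSet as long-format TSV
#'
#' Columns: participant_id, roi_id, value.
#' @param x a [ROISampleSet-class]
#' @param path TSV file
#' @export
writeROISamplesTSV <- function(x, path) {
  rt <- roiTable(x@parcellation)
  rows <- lapply(names(x@samples), function(pid) {
    s <- x@samples[[pid]]
    data.frame(participant_id = pid,
               roi_id = rep(rt$roi_id, lengths(s)),
               value = unlist(s, use.names = FALSE))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeROISamplesTSV
#' @param parc parcellation the table is keyed to
#' @param minVoxels minimum voxels per (participant, ROI) cell
#' @export
readROISamplesTSV <- function(path, parc, minVoxels = 10) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  roiSampleSetFromLong(df, parc, minVoxels = minVoxels)
}

#' Extract per-ROI voxel samples from gray-matter images and an atlas
#'
#' For each participant image and each parcellation ROI, collects the
#' gray-matter intensities of the voxels whose atlas label equals the ROI id.
#' The images must be smoothed modulated gray-matter maps already normalized
#' to the atlas grid (segmentation/normalization is upstream of this
#' package).
#'
#' @param gmImages character vector of NIfTI paths, named by participant id
#'   (unnamed: the file base name is used). Order does not matter; the
#'   resulting set is keyed and sorted by id.
#' @param atlasImage integer-labeled NIfTI on the same grid
#' @param parc a [Parcellation-class]; every `roi_id` must occur in the atlas
#' @param minVoxels minimum voxels per ROI
#' @return a [ROISampleSet-class]
#' @export
extractROISamples <- function(gmImages, atlasImage, parc, minVoxels = 10) {
  atlas <- RNifti::readNifti(atlasImage)
  adim <- dim(atlas)
  rt <- roiTable(parc)
  lab <- as.integer(round(as.vector(atlas)))
  idx <- lapply(rt$roi_id, function(id) which(lab == id))
  missing <- rt$roi_id[lengths(idx) == 0]
  if (length(missing))
    stop("atlas is missing roi_id(s): ", paste(missing, collapse = ", "))
  small <- which(lengths(idx) < minVoxels)
  if (length(small))
    stop("ROI(s) below minVoxels in atlas: ",
         paste(rt$name[small], collapse = ", "))
  ids <- names(gmImages)
  if (is.null(ids)) ids <- sub("\\.nii(\\.gz)?$", "", basename(gmImages))
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  ord <- order(ids)
  samples <- vector("list", length(ids))
  names(samples) <- ids[ord]
  for (k in seq_along(ord)) {
    f <- gmImages[ord[k]]
    img <- RNifti::readNifti(f)
    if (!identical(dim(img), adim))
      stop("grid mismatch between ", basename(f), " and atlas (",
           paste(dim(img), collapse = "x"), " vs ",
           paste(adim, collapse = "x"), ")")
    v <- as.vector(img)
    s <- lapply(idx, function(i) v[i])
    if (any(vapply(s, function(z) any(is.na(z)), logical(1))))
      stop("NaN gray-matter intensities in ", basename(f))
    names(s) <- rt$name
    samples[[k]] <- s
  }
  ROISampleSet(samples, parc)
}

#' Regional gray-matter volume features
#'
#' GMV per (participant, ROI): the sum of voxel intensities times the voxel
#' volume (conventional modulated-VBM regional volume, the default), or the
#' mean voxel intensity (`mode = "mean"`).
#'
#' @param samples a [ROISampleSet-class]
#' @param voxelVolume voxel volume in mm^3 (ignored for `mode = "mean"`)
#' @param mode `"sum"` or `"mean"`
#' @return participants x ROIs matrix, columns in parcellation order
#' @export
computeGMV <- function(samples, voxelVolume = 1, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  .assertScalarNum(voxelVolume, "voxelVolume")
  ids <- participants(samples)
  rn <- roiNames(samples)
  out <- matrix(NA_real_, length(ids), length(rn), dimnames = list(ids, rn))
  for (pid in ids) {
    s <- samples@samples[[pid]]
    if (any(lengths(s) == 0)) stop("empty sample vector for participant ", pid)
    out[pid, ] <- if (mode == "sum")
      vapply(s, sum, numeric(1)) * voxelVolume
    else vapply(s, mean, numeric(1))
  }
  out
}
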