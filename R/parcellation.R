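#' Construct a parcellation from a table
#'
#' @param rois data.frame with columns `roi_id`, `name`, `hemisphere`, `lobe`.
#' @return a [Parcellation-class]
#' @export
Parcellation <- function(rois) {
  rois <- as.data.frame(rois, stringsAsFactors = FALSE)
  rownames(rois) <- NULL
  new("Parcellation", rois = rois)
}

#' Load a parcellation table from CSV
#'
#' The file must have columns `roi_id`, `name`, `hemisphere` (`L`/`R`) and
#' `lobe` (one of the eight lobe labels: prefrontal, motorstrip, insula,
#' parietal, temporal, occipital, limbic, subcortical). Row order defines the
#' canonical feature order.
#'
#' @param path CSV file path
#' @return a [Parcellation-class]
#' @export
loadParcellation <- function(path) {
  if (!file.exists(path)) stop("parcellation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  Parcellation(df)
}

#' The packaged 90-ROI AAL-based parcellation
#'
#' The 90 cerebral AAL regions (cerebellum excluded) grouped into 16
#' hemisphere-specific lobes (8 lobe labels x 2 hemispheres). The lobe
#' assignment shipped here is the package's own coordinate-convention
#' reconstruction of the usual circle-plot grouping, not a published lookup
#' table; pass your own CSV to [loadParcellation()] to override it.
#'
#' @return a [Parcellation-class] with 90 ROIs
#' @export
defaultParcellation <- function() {
  loadParcellation(system.file("extdata", "aal90_lobes_reconstructed.csv",
                               package = "painMC", mustWork = TRUE))
}

#' Synthetic parcellation for simulated cohorts
#'
#' Generic ROI labels with hemispheres alternating L/R and lobes cycling
#' through the eight lobe labels, so lobe-pair summaries are exercisable on
#' simulated data of any size.
#'
#' @param nRois number of ROIs (>= 3)
#' @return a [Parcellation-class]
#' @export
syntheticParcellation <- function(nRois) {
  nRois <- as.integer(nRois)
  if (nRois < 3) stop("nRois must be >= 3")
  hemi <- rep(c("L", "R"), length.out = nRois)
  lobe <- rep(.LOBE_LEVELS, each = 2, length.out = nRois)
  Parcellation(data.frame(
    roi_id = seq_len(nRois),
    name = sprintf("ROI_%02d_%s", seq_len(nRois), hemi),
    hemisphere = hemi, lobe = lobe, stringsAsFactors = FALSE))
}

#' @describeIn Parcellation number of ROIs
#' @param x a Parcellation
#' @export
setMethod("nRois", "Parcellation", function(x) nrow(x@rois))

#' @describeIn Parcellation ROI names in canonical order
#' @export
setMethod("roiNames", "Parcellation", function(x) x@rois$name)

#' ROI table of a parcellation
#' @param parc a [Parcellation-class]
#' @return data.frame with roi_id, name, hemisphere, lobe
#' @export
roiTable <- function(parc) parc@rois

#' Hemisphere-specific lobe label of each ROI
#'
#' @param parc a [Parcellation-class]
#' @return character vector like `"Prefrontal_L"`, in parcellation order
#' @export
lobeLabels <- function(parc) {
  df <- parc@rois
  paste0(toupper(substring(df$lobe, 1, 1)), substring(df$lobe, 2),
         "_", df$hemisphere)
}

setMethod("show", "Parcellation", function(object) {
  df <- object@rois
  cat("Parcellation with", nrow(df), "ROIs,",
      length(unique(paste(df$hemisphere, df$lobe))), "hemisphere-lobe groups\n")
})
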