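#' Number of ROIs
#' @param x a [Parcellation-class] or [ROISampleSet-class]
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' ROI names in canonical order
#' @param x a [Parcellation-class] or [ROISampleSet-class]
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' Participant identifiers
#' @param x a [ROISampleSet-class]
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))

#' Voxel intensity samples of one (participant, ROI) cell
#' @param x a [ROISampleSet-class]
#' @param participant participant id
#' @param roi ROI name (or omit for the named list of all ROIs)
#' @export
setGeneric("roiSamples",
           function(x, participant, roi) standardGeneric("roiSamples"))

#' Selected feature indices of a [SelectionResult-class]
#' @param x a [SelectionResult-class]
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' Search trace of a [SelectionResult-class]
#' @param x a [SelectionResult-class]
#' @export
setGeneric("searchTrace", function(x) standardGeneric("searchTrace"))
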