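#' @rdname MoleculeStructure-class
#' @param object,x a poseforge object.
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))

#' @rdname MoleculeStructure-class
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' @rdname MoleculeStructure-class
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname MoleculeStructure-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname PoseSet-class
#' @export
setGeneric("complexId", function(x) standardGeneric("complexId"))

#' @rdname PoseSet-class
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))

#' @rdname PoseSet-class
#' @export
setGeneric("nativePose", function(x) standardGeneric("nativePose"))

#' @rdname PoseSet-class
#' @export
setGeneric("candidatePoses", function(x) standardGeneric("candidatePoses"))

#' @rdname PoseSet-class
#' @export
setGeneric("poseEnergies", function(x) standardGeneric("poseEnergies"))

#' @rdname PoseSet-class
#' @export
setGeneric("rmsdToNative", function(x) standardGeneric("rmsdToNative"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureFamilies", function(x) standardGeneric("featureFamilies"))

#' @rdname DecoySet-class
#' @export
setGeneric("decoyManifest", function(x) standardGeneric("decoyManifest"))

#' @rdname DecoySet-class
#' @export
setGeneric("representativePoses", function(x) standardGeneric("representativePoses"))

#' @rdname SuccessRateReport-class
#' @export
setGeneric("successRates", function(x) standardGeneric("successRates"))

#' @rdname SuccessRateReport-class
#' @export
setGeneric("hitMatrix", function(x) standardGeneric("hitMatrix"))
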