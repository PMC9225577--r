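#' @rdname FoldChangeMatrix-class
#' @export
setGeneric("foldChanges", function(object) standardGeneric("foldChanges"))

#' @rdname FoldChangeMatrix-class
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname FoldChangeMatrix-class
#' @export
setGeneric("alphaLevel", function(object) standardGeneric("alphaLevel"))

#' @rdname InteractionMatrix-class
#' @export
setGeneric("interactionStrengths",
           function(object) standardGeneric("interactionStrengths"))

#' @rdname InteractionMatrix-class
#' @export
setGeneric("interactionType",
           function(object) standardGeneric("interactionType"))

#' @rdname InteractionMatrix-class
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

#' @rdname PeakHeightExperiment-class
#' @export
setGeneric("tableKind", function(object) standardGeneric("tableKind"))

#' @rdname PeakHeightExperiment-class
#' @export
setGeneric("analyteIds", function(object) standardGeneric("analyteIds"))

#' @rdname PeakHeightExperiment-class
#' @export
setGeneric("sampleRoles", function(object) standardGeneric("sampleRoles"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("consumptionMatrix",
           function(object) standardGeneric("consumptionMatrix"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("secretionMatrix",
           function(object) standardGeneric("secretionMatrix"))
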