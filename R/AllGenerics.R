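#' @rdname SpectraSet-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("bandLabel", function(x) standardGeneric("bandLabel"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("nWavelengths", function(x) standardGeneric("nWavelengths"))

#' @rdname ReferenceTable-accessors
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @rdname ReferenceTable-accessors
#' @export
setGeneric("traitValues", function(x, trait) standardGeneric("traitValues"))

#' @rdname CVResult-accessors
#' @export
setGeneric("optimalLV", function(x) standardGeneric("optimalLV"))

#' @rdname CVResult-accessors
#' @export
setGeneric("rmsecvCurve", function(x) standardGeneric("rmsecvCurve"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("selectedWavelengths", function(x) {
  standardGeneric("selectedWavelengths")
})

#' @rdname SelectionResult-accessors
#' @export
setGeneric("selectionImportance", function(x) {
  standardGeneric("selectionImportance")
})
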