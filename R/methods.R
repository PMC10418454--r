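#' Accessors for SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @name SpectraSet-accessors
#' @aliases wavelengths intensities bandLabel sampleIds nSamples nWavelengths
NULL

#' @rdname SpectraSet-accessors
setMethod("wavelengths", "SpectraSet", function(x) x@wavelengths)

#' @rdname SpectraSet-accessors
setMethod("intensities", "SpectraSet", function(x) {
  m <- x@intensities
  dimnames(m) <- list(x@sampleIds, NULL)
  m
})

#' @rdname SpectraSet-accessors
setMethod("bandLabel", "SpectraSet", function(x) x@bandLabel)

#' @rdname SpectraSet-accessors
setMethod("sampleIds", "SpectraSet", function(x) x@sampleIds)

#' @rdname SpectraSet-accessors
setMethod("nSamples", "SpectraSet", function(x) nrow(x@intensities))

#' @rdname SpectraSet-accessors
setMethod("nWavelengths", "SpectraSet", function(x) length(x@wavelengths))

#' Subset a SpectraSet
#'
#' `x[i, j]` keeps samples `i` and wavelength columns `j`.
#'
#' @param x a [SpectraSet-class].
#' @param i sample index (integer/logical/character ids).
#' @param j wavelength column index.
#' @param ... ignored.
#' @param drop ignored; a SpectraSet is always returned.
#' @export
setMethod("[", "SpectraSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nWavelengths(x))
  if (is.character(i)) i <- match(i, x@sampleIds)
  SpectraSet(
    x@wavelengths[j], x@intensities[i, j, drop = FALSE],
    x@bandLabel, x@sampleIds[i]
  )
})

setMethod("show", "SpectraSet", function(object) {
  wl <- object@wavelengths
  cat(sprintf(
    "SpectraSet [%s]: %d samples x %d wavelengths (%.4g-%.4g nm)\n",
    object@bandLabel, nSamples(object), nWavelengths(object),
    min(wl), max(wl)
  ))
})

#' Accessors for ReferenceTable
#'
#' @param x a [ReferenceTable-class].
#' @param trait trait name, one of the table's columns.
#' @name ReferenceTable-accessors
#' @aliases traitNames traitValues
NULL

#' @rdname ReferenceTable-accessors
setMethod("traitNames", "ReferenceTable", function(x) colnames(x@traits))

#' @rdname ReferenceTable-accessors
setMethod("traitValues", "ReferenceTable", function(x, trait) {
  if (!trait %in% colnames(x@traits)) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  as.numeric(x@traits[, trait])
})

#' @rdname ReferenceTable-accessors
setMethod("sampleIds", "ReferenceTable", function(x) x@sampleIds)

#' @rdname ReferenceTable-accessors
setMethod("nSamples", "ReferenceTable", function(x) length(x@sampleIds))

#' Subset a ReferenceTable by sample
#'
#' @param x a [ReferenceTable-class].
#' @param i sample index (integer/logical/character ids).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ReferenceTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  ReferenceTable(x@sampleIds[i], x@traits[i, , drop = FALSE])
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf(
    "ReferenceTable: %d samples, traits: %s\n",
    nSamples(object), paste(traitNames(object), collapse = ", ")
  ))
})

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf(
    "PLSRModel: %d latent variables, p = %d predictors\n",
    object@nLV, length(object@beta)
  ))
})

#' Accessors for CVResult
#'
#' @param x a [CVResult-class].
#' @name CVResult-accessors
#' @aliases optimalLV rmsecvCurve
NULL

#' @rdname CVResult-accessors
setMethod("optimalLV", "CVResult", function(x) x@optimalLV)

#' @rdname CVResult-accessors
setMethod("rmsecvCurve", "CVResult", function(x) x@rmsecvByLV)

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: optimal LV = %d (RMSECV = %.4g, Rcv = %.3f)%s\n",
    object@optimalLV, object@rmsecvByLV[object@optimalLV], object@rCv,
    if (object@truncated) " [curve truncated by rank deficiency]" else ""
  ))
})

#' Accessors for SelectionResult
#'
#' @param x a [SelectionResult-class].
#' @name SelectionResult-accessors
#' @aliases selectedWavelengths selectionImportance
NULL

#' @rdname SelectionResult-accessors
setMethod("selectedWavelengths", "SelectionResult", function(x) x@selectedNm)

#' @rdname SelectionResult-accessors
setMethod("selectionImportance", "SelectionResult", function(x) x@importance)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult [%s]: %d wavelengths (%s nm)%s\n",
    object@method, length(object@selectedNm),
    paste(signif(object@selectedNm, 6), collapse = ", "),
    if (object@shortfall) " [shortfall]" else ""
  ))
})
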