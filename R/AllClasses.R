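#' @import methods
NULL

TRAIT_NAMES <- c("fat", "protein", "collagen", "ash", "Na")

#' SpectraSet: a sample-by-wavelength spectral matrix
#'
#' Container for one band of reflectance (or transformed) spectra: an
#' \code{n_samples x n_wavelengths} intensity matrix together with its
#' wavelength grid in nanometres, a band label and unique sample ids.
#' Wavelengths are strictly increasing and all intensities must be finite.
#'
#' @slot wavelengths numeric, strictly increasing grid in nm.
#' @slot intensities numeric matrix, rows = samples, columns = wavelengths.
#' @slot bandLabel character(1), one of \code{"VNIR"}, \code{"NIR"},
#'   \code{"merged"}.
#' @slot sampleIds character, unique sample identifiers (row order).
#' @exportClass SpectraSet
setClass("SpectraSet",
  slots = c(
    wavelengths = "numeric",
    intensities = "matrix",
    bandLabel = "character",
    sampleIds = "character"
  )
)

setValidity("SpectraSet", function(object) {
  msg <- character()
  wl <- object@wavelengths
  m <- object@intensities
  if (length(wl) == 0L) msg <- c(msg, "empty wavelength grid")
  if (anyNA(wl) || any(!is.finite(wl))) msg <- c(msg, "non-finite wavelengths")
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    msg <- c(msg, "wavelengths must be strictly increasing with no duplicates")
  }
  if (ncol(m) != length(wl)) {
    msg <- c(msg, "column count of intensities must equal length(wavelengths)")
  }
  if (nrow(m) != length(object@sampleIds)) {
    msg <- c(msg, "row count of intensities must equal length(sampleIds)")
  }
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "non-finite intensity for sample '%s' at %.4g nm",
      object@sampleIds[bad[1L]], wl[bad[2L]]
    ))
  }
  if (length(object@bandLabel) != 1L ||
    !object@bandLabel %in% c("VNIR", "NIR", "merged")) {
    msg <- c(msg, "bandLabel must be one of 'VNIR', 'NIR', 'merged'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param wavelengths numeric wavelength grid (nm); will be used as given
#'   and must be strictly increasing.
#' @param intensities numeric matrix, samples in rows.
#' @param bandLabel `"VNIR"`, `"NIR"` or `"merged"`.
#' @param sampleIds character vector of unique ids; defaults to
#'   `rownames(intensities)` or `S1..Sn`.
#' @return A validated [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(c(650, 650.35, 650.7), matrix(rnorm(6), 2), "VNIR")
#' nWavelengths(s)
#' @export
SpectraSet <- function(wavelengths, intensities, bandLabel,
                       sampleIds = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(sampleIds)) {
    sampleIds <- rownames(intensities)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(intensities)))
  }
  dimnames(intensities) <- NULL
  new("SpectraSet",
    wavelengths = as.numeric(wavelengths), intensities = intensities,
    bandLabel = bandLabel, sampleIds = as.character(sampleIds)
  )
}

#' ReferenceTable: wet-chemistry trait values per sample
#'
#' Holds the reference values (g/kg) of the five quality traits
#' (fat, protein, collagen, ash, Na) used as PLSR responses.
#'
#' @slot sampleIds character, unique sample identifiers.
#' @slot traits numeric matrix, one column per trait, rows aligned with
#'   \code{sampleIds}; all values finite and non-negative.
#' @exportClass ReferenceTable
setClass("ReferenceTable",
  slots = c(sampleIds = "character", traits = "matrix")
)

setValidity("ReferenceTable", function(object) {
  msg <- character()
  tr <- object@traits
  if (nrow(tr) != length(object@sampleIds)) {
    msg <- c(msg, "trait rows must match sampleIds")
  }
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  if (is.null(colnames(tr)) || anyDuplicated(colnames(tr))) {
    msg <- c(msg, "traits must have unique column names")
  }
  if (!all(is.finite(tr))) msg <- c(msg, "non-finite trait values")
  else if (any(tr < 0)) msg <- c(msg, "negative trait values")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceTable
#'
#' @param sampleIds character vector of unique ids.
#' @param traits numeric matrix or data.frame of trait values (g/kg),
#'   one named column per trait.
#' @return A validated [ReferenceTable-class].
#' @export
ReferenceTable <- function(sampleIds, traits) {
  traits <- as.matrix(as.data.frame(traits))
  rownames(traits) <- NULL
  new("ReferenceTable", sampleIds = as.character(sampleIds), traits = traits)
}

#' PLSRModel: a fitted NIPALS partial least squares regression
#'
#' Single-response PLSR fitted by NIPALS on mean-centred data. Prediction
#' uses the assembled regression vector: \code{yhat = intercept + X beta}.
#'
#' @slot xMean numeric p-vector of training column means.
#' @slot yMean numeric(1) training response mean.
#' @slot weights p x A weight matrix W (unit-norm columns).
#' @slot xLoadings p x A loading matrix P.
#' @slot yLoadings numeric A-vector q.
#' @slot scores n x A training score matrix T (mutually orthogonal columns).
#' @slot nLV integer(1), number of latent variables A.
#' @slot beta numeric p-vector of regression coefficients on raw-scale X.
#' @slot intercept numeric(1).
#' @slot wavelengths numeric grid the model was fitted on (may be empty).
#' @exportClass PLSRModel
setClass("PLSRModel",
  slots = c(
    xMean = "numeric", yMean = "numeric",
    weights = "matrix", xLoadings = "matrix", yLoadings = "numeric",
    scores = "matrix", nLV = "integer", beta = "numeric",
    intercept = "numeric", wavelengths = "numeric"
  )
)

setValidity("PLSRModel", function(object) {
  msg <- character()
  A <- object@nLV
  p <- length(object@xMean)
  if (A < 1L) msg <- c(msg, "nLV must be >= 1")
  if (ncol(object@weights) != A || ncol(object@xLoadings) != A ||
    length(object@yLoadings) != A || ncol(object@scores) != A) {
    msg <- c(msg, "factor matrices must have nLV columns")
  }
  if (length(object@beta) != p) msg <- c(msg, "beta length must equal p")
  if (length(object@wavelengths) && length(object@wavelengths) != p) {
    msg <- c(msg, "wavelengths, when set, must have length p")
  }
  if (length(msg)) msg else TRUE
})

#' CVResult: leave-one-out cross-validation summary for LV selection
#'
#' @slot rmsecvByLV numeric vector, RMSECV for 1..A_max latent variables.
#' @slot optimalLV integer(1), argmin of the curve (ties broken toward
#'   fewer LVs).
#' @slot rCv numeric(1), correlation of LOOCV predictions with the
#'   response at the optimal LV count.
#' @slot predictions numeric matrix of LOOCV predictions (n x A_max).
#' @slot truncated logical(1), TRUE when rank deficiency in some fold
#'   shortened the curve below the requested A_max.
#' @exportClass CVResult
setClass("CVResult",
  slots = c(
    rmsecvByLV = "numeric", optimalLV = "integer", rCv = "numeric",
    predictions = "matrix", truncated = "logical"
  )
)

setValidity("CVResult", function(object) {
  a <- object@optimalLV
  if (a < 1L || a > length(object@rmsecvByLV)) {
    return("optimalLV outside the curve")
  }
  if (object@rmsecvByLV[a] > min(object@rmsecvByLV) + 1e-12) {
    return("optimalLV must attain the minimum RMSECV")
  }
  TRUE
})

#' SelectionResult: wavelengths chosen by a variable-selection method
#'
#' @slot method character(1), `"RC"` (regression-coefficient extrema) or
#'   `"RF"` (random frog).
#' @slot selectedNm numeric, chosen wavelengths (nm), ascending, always a
#'   subset of the model grid.
#' @slot importance numeric, score per selected wavelength: absolute
#'   regression coefficient for RC, selection probability in [0, 1] for RF.
#' @slot nRequested integer(1), number of wavelengths asked for.
#' @slot seed numeric(1), RNG seed used (NA for deterministic methods).
#' @slot shortfall logical(1), TRUE when fewer than nRequested could be
#'   returned (e.g. too few coefficient extrema).
#' @exportClass SelectionResult
setClass("SelectionResult",
  slots = c(
    method = "character", selectedNm = "numeric", importance = "numeric",
    nRequested = "integer", seed = "numeric", shortfall = "logical"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (!object@method %in% c("RC", "RF")) msg <- c(msg, "method must be RC or RF")
  if (is.unsorted(object@selectedNm, strictly = TRUE)) {
    msg <- c(msg, "selectedNm must be strictly ascending")
  }
  if (length(object@importance) != length(object@selectedNm)) {
    msg <- c(msg, "importance must align with selectedNm")
  }
  if (object@method == "RF" &&
    any(object@importance < 0 | object@importance > 1)) {
    msg <- c(msg, "RF selection probabilities must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
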