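#' Preprocessing specification
#'
#' Names one of the five screened spectral preprocessings and its
#' parameters. Savitzky-Golay derivatives use a second-order polynomial in
#' a 15-point moving window by default; SNVD detrends with a degree-2
#' polynomial after SNV.
#'
#' @param name one of `"none"`, `"SNV"`, `"SNVD"`, `"Der1"`, `"Der2"`.
#' @param sgWindow odd window length in points (> `sgPolyorder`).
#' @param sgPolyorder Savitzky-Golay polynomial order.
#' @param detrendDegree polynomial degree for the detrend step of SNVD.
#' @return A `PreprocSpec` list.
#' @export
preprocSpec <- function(name = c("none", "SNV", "SNVD", "Der1", "Der2"),
                        sgWindow = 15L, sgPolyorder = 2L,
                        detrendDegree = 2L) {
  name <- match.arg(name)
  sgWindow <- as.integer(sgWindow)
  if (sgWindow %% 2L == 0L || sgWindow <= sgPolyorder) {
    stop("sgWindow must be odd and greater than sgPolyorder")
  }
  if (detrendDegree < 1L) stop("detrendDegree must be >= 1")
  structure(
    list(
      name = name, sgWindow = sgWindow,
      sgPolyorder = as.integer(sgPolyorder),
      detrendDegree = as.integer(detrendDegree)
    ),
    class = "PreprocSpec"
  )
}

#' Standard normal variate transform
#'
#' Row-wise: subtract the spectrum's mean and divide by its standard
#' deviation (n-1 denominator). Removes per-sample multiplicative scatter
#' and additive offset; invariant to positive affine transforms of each
#' spectrum.
#'
#' @param s a [SpectraSet-class] with at least two wavelengths.
#' @return The transformed [SpectraSet-class] on the same grid.
#' @export
snv <- function(s) {
  m <- s@intensities
  if (ncol(m) < 2L) stop("SNV needs at least two wavelengths")
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  if (any(sd <= 0)) {
    stop(
      "zero-variance spectrum for sample(s): ",
      paste(sampleIds(s)[sd <= 0], collapse = ", ")
    )
  }
  SpectraSet(wavelengths(s), (m - mu) / sd, bandLabel(s), sampleIds(s))
}

#' Polynomial detrend
#'
#' Per spectrum, fits a least-squares polynomial of the given degree in
#' wavelength (nm) and returns the residual, suppressing baseline shift
#' and curvature.
#'
#' @param s a [SpectraSet-class].
#' @param degree polynomial degree (default 2); must be below
#'   `nWavelengths(s) - 1`.
#' @return The detrended [SpectraSet-class].
#' @export
detrendSpectra <- function(s, degree = 2L) {
  p <- nWavelengths(s)
  if (degree >= p) stop("detrend fit underdetermined: degree too high")
  # orthonormal polynomial basis in nm, shared by all rows
  lam <- scale(wavelengths(s))[, 1L]
  D <- stats::poly(lam, degree = degree, raw = FALSE)
  Q <- qr.Q(qr(cbind(1, D)))
  m <- s@intensities
  resid <- m - (m %*% Q) %*% t(Q)
  SpectraSet(wavelengths(s), resid, bandLabel(s), sampleIds(s))
}

#' SNV followed by detrend
#'
#' Barnes-style SNVD: [snv()] then a degree-`detrendDegree` polynomial
#' [detrendSpectra()].
#'
#' @param s a [SpectraSet-class].
#' @param detrendDegree detrend polynomial degree (default 2).
#' @return The transformed [SpectraSet-class].
#' @export
snvd <- function(s, detrendDegree = 2L) {
  detrendSpectra(snv(s), degree = detrendDegree)
}

#' Savitzky-Golay derivative
#'
#' Per spectrum, convolves with Savitzky-Golay coefficients (polynomial
#' order and window from `spec`) and returns the first or second
#' derivative scaled by the physical grid pitch, i.e. in intensity per
#' nm^derivOrder, so the two instrument bands are comparable. The grid
#' must be uniform within 1% relative tolerance. No edge values are
#' fabricated: `(window - 1) / 2` points are dropped at each end.
#'
#' @param s a [SpectraSet-class].
#' @param spec a [preprocSpec()] providing `sgWindow` and `sgPolyorder`.
#' @param derivOrder 1 or 2.
#' @return A [SpectraSet-class] on the edge-trimmed grid.
#' @export
savgolDerivative <- function(s, spec = preprocSpec("Der1"), derivOrder = 1L) {
  stopifnot(derivOrder %in% c(1L, 2L))
  wl <- wavelengths(s)
  w <- spec$sgWindow
  if (length(wl) < w) stop("window longer than spectrum")
  pitch <- diff(wl)
  mpitch <- mean(pitch)
  if (max(abs(pitch - mpitch)) > 0.01 * mpitch) {
    stop("wavelength grid not uniform within 1% relative tolerance")
  }
  fm <- signal::sgolay(
    p = spec$sgPolyorder, n = w, m = derivOrder,
    ts = mpitch
  )
  coeffs <- fm[(w + 1L) %/% 2L, ] # central filter row
  half <- (w - 1L) %/% 2L
  m <- s@intensities
  # each output column j is the window m[, j .. j + w - 1] times coeffs
  out <- matrix(0, nrow(m), ncol(m) - w + 1L)
  vrev <- rev(coeffs)
  for (i in seq_len(nrow(m))) {
    out[i, ] <- embed(m[i, ], w) %*% vrev
  }
  keep <- seq.int(half + 1L, length(wl) - half)
  SpectraSet(wl[keep], out, bandLabel(s), sampleIds(s))
}

#' Apply a named preprocessing
#'
#' Dispatch helper used by the screening grid: `"none"` returns the input
#' unchanged, `"SNV"`/`"SNVD"` the scatter corrections, `"Der1"`/`"Der2"`
#' the Savitzky-Golay derivatives.
#'
#' @param s a [SpectraSet-class].
#' @param spec a [preprocSpec()] (or a bare name, converted with
#'   defaults).
#' @return The transformed [SpectraSet-class].
#' @export
applyPreprocessing <- function(s, spec) {
  if (is.character(spec)) spec <- preprocSpec(spec)
  switch(spec$name,
    none = s,
    SNV = snv(s),
    SNVD = snvd(s, spec$detrendDegree),
    Der1 = savgolDerivative(s, spec, 1L),
    Der2 = savgolDerivative(s, spec, 2L)
  )
}
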