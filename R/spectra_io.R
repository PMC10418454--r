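#' Read a wide-format spectral CSV
#'
#' The canonical on-disk layout is `sample_id,<nm>,<nm>,...` with one row
#' per sample and numeric wavelength headers in nanometres. Columns are
#' reordered to ascending wavelength on ingestion; any non-numeric header,
#' duplicate sample id or non-finite cell is rejected.
#'
#' @param path path to the CSV file.
#' @param bandLabel band identity to attach: `"VNIR"`, `"NIR"` or
#'   `"merged"`.
#' @return A validated [SpectraSet-class].
#' @seealso [writeSpectraCSV()], [trimNoiseBands()]
#' @export
readSpectraCSV <- function(path, bandLabel) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectral CSV needs an id column plus wavelengths")
  wl <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(wl)) {
    stop(
      "non-numeric wavelength header(s): ",
      paste(names(df)[-1L][is.na(wl)], collapse = ", ")
    )
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]),
      collapse = ", "
    ))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite value for sample '%s' at %s nm",
      ids[bad[1L]], names(df)[-1L][bad[2L]]
    ))
  }
  ord <- order(wl)
  SpectraSet(wl[ord], m[, ord, drop = FALSE], bandLabel, ids)
}

#' Write a SpectraSet to wide-format CSV
#'
#' @param s a [SpectraSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectraCSV <- function(s, path) {
  df <- data.frame(sample_id = sampleIds(s), check.names = FALSE)
  m <- s@intensities
  colnames(m) <- format(wavelengths(s), trim = TRUE, digits = 15)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference trait CSV
#'
#' Layout: `sample_id,fat,protein,collagen,ash,Na`, values in g/kg.
#'
#' @param path path to the CSV file.
#' @return A validated [ReferenceTable-class].
#' @export
readReferenceCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  ReferenceTable(ids, df[, -1L, drop = FALSE])
}

#' Write a ReferenceTable to CSV
#'
#' @param refs a [ReferenceTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReferenceCSV <- function(refs, path) {
  df <- cbind(
    data.frame(sample_id = sampleIds(refs)),
    as.data.frame(refs@traits)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Band-keep specification
#'
#' Closed wavelength intervals to retain when trimming instrument noise
#' bands. The two instrument bands keep 650-950 nm (VNIR) and 960-1660 nm (NIR);
#' the regions outside them (below 650 nm, 942.7-960 nm, above the NIR
#' band) are dominated by detector noise and are excluded.
#'
#' @param keepRanges numeric matrix or list of `c(low, high)` pairs (nm);
#'   closed on both ends, non-overlapping, low < high.
#' @param label band name for the trimmed result.
#' @return A `BandSpec` list (`keepRanges`, `label`).
#' @examples
#' bandSpec(c(650, 950), "VNIR")
#' @export
bandSpec <- function(keepRanges, label) {
  if (is.numeric(keepRanges) && is.null(dim(keepRanges))) {
    keepRanges <- matrix(keepRanges, ncol = 2L, byrow = TRUE)
  }
  if (is.list(keepRanges)) keepRanges <- do.call(rbind, keepRanges)
  keepRanges <- keepRanges[order(keepRanges[, 1L]), , drop = FALSE]
  if (any(keepRanges[, 1L] >= keepRanges[, 2L])) {
    stop("each keep interval needs low < high")
  }
  if (nrow(keepRanges) > 1L &&
    any(keepRanges[-1L, 1L] <= keepRanges[-nrow(keepRanges), 2L])) {
    stop("keep intervals must not overlap")
  }
  structure(list(keepRanges = keepRanges, label = label),
    class = "BandSpec"
  )
}

#' Default keep intervals for the two instrument bands
#'
#' @param band `"VNIR"` (keeps 650-950 nm) or `"NIR"` (keeps 960-1660 nm).
#' @return A [bandSpec()].
#' @export
defaultBandSpec <- function(band = c("VNIR", "NIR")) {
  band <- match.arg(band)
  switch(band,
    VNIR = bandSpec(c(650, 950), "VNIR"),
    NIR = bandSpec(c(960, 1660), "NIR")
  )
}

#' Trim high-noise wavebands from a SpectraSet
#'
#' Retains only wavelengths falling inside one of the closed keep
#' intervals of `spec`; sample rows are untouched.
#'
#' @param raw a [SpectraSet-class].
#' @param spec a [bandSpec()].
#' @return The trimmed [SpectraSet-class], relabelled with `spec$label`.
#' @export
trimNoiseBands <- function(raw, spec) {
  stopifnot(inherits(spec, "BandSpec"))
  wl <- wavelengths(raw)
  keep <- rep(FALSE, length(wl))
  for (k in seq_len(nrow(spec$keepRanges))) {
    keep <- keep | (wl >= spec$keepRanges[k, 1L] &
      wl <= spec$keepRanges[k, 2L])
  }
  if (!any(keep)) stop("trimming removed every wavelength (empty band)")
  SpectraSet(
    wl[keep], raw@intensities[, keep, drop = FALSE],
    spec$label, sampleIds(raw)
  )
}

#' Average replicate spectra
#'
#' Element-wise arithmetic mean of replicate measurements (e.g. three
#' probe positions x three repeats per sample). All replicates must share
#' the wavelength grid and sample ids. Because the mean is associative,
#' averaging all nine spectra in one pass equals averaging position means
#' of repeat means.
#'
#' @param stack list of [SpectraSet-class] replicates.
#' @return A single averaged [SpectraSet-class].
#' @export
averageReplicates <- function(stack) {
  if (!length(stack)) stop("need at least one replicate set")
  ref <- stack[[1L]]
  for (s in stack[-1L]) {
    if (length(wavelengths(s)) != length(wavelengths(ref)) ||
      any(abs(wavelengths(s) - wavelengths(ref)) > 1e-9)) {
      stop("replicate wavelength grids differ")
    }
    if (!identical(sampleIds(s), sampleIds(ref))) {
      stop("replicate sample ids differ")
    }
  }
  acc <- Reduce(`+`, lapply(stack, function(s) s@intensities))
  SpectraSet(
    wavelengths(ref), acc / length(stack),
    bandLabel(ref), sampleIds(ref)
  )
}
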