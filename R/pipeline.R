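#' Screen preprocessings across bands and traits
#'
#' Fits one PLSR model per (band, preprocessing, trait) cell: the
#' preprocessed calibration rows choose the LV count by LOOCV, the model
#' is refitted at that count, and calibration, cross-validation and
#' prediction metrics plus RPD are reported. All cells share the same
#' calibration/prediction split; preprocessing operators are per-sample,
#' so applying them before the split leaks nothing. Cell failures are
#' recorded in the `error` column, not fatal.
#'
#' @param spectraList named list of trimmed [SpectraSet-class] objects,
#'   one per band (names become the `band` column).
#' @param refs a [ReferenceTable-class] covering all samples.
#' @param split a [randomSplit()] result.
#' @param traits trait names to model (default: all in `refs`).
#' @param preprocs preprocessing names to screen.
#' @param aMax LOOCV component cap.
#' @return data.frame with one row per cell: band, trait, preprocessing,
#'   nLV, rC, rmsec, rCv, rmsecv, rP, rmsep, rpd, rpdLabel, error.
#' @export
screenPreprocessings <- function(spectraList, refs, split,
                                 traits = traitNames(refs),
                                 preprocs = c(
                                   "none", "SNV", "SNVD", "Der1", "Der2"
                                 ),
                                 aMax = 15L) {
  rows <- list()
  for (band in names(spectraList)) {
    for (pp in preprocs) {
      pre <- tryCatch(applyPreprocessing(spectraList[[band]], pp),
        error = function(e) e
      )
      for (trait in traits) {
        row <- if (inherits(pre, "error")) {
          failedCell(band, trait, pp, conditionMessage(pre))
        } else {
          tryCatch(
            evaluateCell(pre, refs, split, trait, pp, aMax),
            error = function(e) {
              failedCell(band, trait, pp, conditionMessage(e))
            }
          )
        }
        row$band <- band
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out[, c(
    "band", "trait", "preprocessing", "nLV", "rC", "rmsec", "rCv",
    "rmsecv", "rP", "rmsep", "rpd", "rpdLabel", "error"
  )]
}

failedCell <- function(band, trait, pp, msg) {
  list(
    band = band, trait = trait, preprocessing = pp, nLV = NA_integer_,
    rC = NA_real_, rmsec = NA_real_, rCv = NA_real_, rmsecv = NA_real_,
    rP = NA_real_, rmsep = NA_real_, rpd = NA_real_,
    rpdLabel = NA_character_, error = msg
  )
}

# Fit + evaluate one screening cell on preprocessed spectra.
evaluateCell <- function(pre, refs, split, trait, ppName, aMax) {
  calIdx <- match(split$calibrationIds, sampleIds(pre))
  predIdx <- match(split$predictionIds, sampleIds(pre))
  if (anyNA(calIdx) || anyNA(predIdx)) {
    stop("split ids missing from the spectra")
  }
  X <- intensities(pre)
  y <- traitValues(refs, trait)[match(sampleIds(pre), sampleIds(refs))]
  xc <- X[calIdx, , drop = FALSE]
  yc <- y[calIdx]
  cv <- suppressWarnings(loocvSelectLV(xc, yc, aMax))
  fit <- fitPLSR(xc, yc, optimalLV(cv), wavelengths = wavelengths(pre))
  calM <- regressionMetrics(yc, predict(fit, xc))
  yp <- y[predIdx]
  predM <- regressionMetrics(yp, predict(fit, X[predIdx, , drop = FALSE]))
  rpdRes <- rpd(stats::sd(yp), predM$rmse)
  list(
    band = bandLabel(pre), trait = trait, preprocessing = ppName,
    nLV = optimalLV(cv), rC = calM$r, rmsec = calM$rmse, rCv = cv@rCv,
    rmsecv = rmsecvCurve(cv)[optimalLV(cv)], rP = predM$r,
    rmsep = predM$rmse, rpd = rpdRes$rpd, rpdLabel = rpdRes$label,
    error = NA_character_
  )
}

#' Optimal screening cell per trait
#'
#' Picks, for each trait (optionally within each band), the cell with
#' the smallest RMSECV. Choosing on the cross-validated calibration
#' error, not on prediction-set performance, keeps the prediction set
#' untouched until final evaluation.
#'
#' @param reports data.frame from [screenPreprocessings()].
#' @param perBand if TRUE, one winner per trait and band; otherwise one
#'   per trait.
#' @return Subset of `reports` rows (the winners).
#' @export
optimalCells <- function(reports, perBand = FALSE) {
  ok <- reports[is.na(reports$error), , drop = FALSE]
  key <- if (perBand) {
    interaction(ok$trait, ok$band, drop = TRUE)
  } else {
    factor(ok$trait)
  }
  ok[unlist(lapply(split(seq_len(nrow(ok)), key), function(i) {
    i[which.min(ok$rmsecv[i])]
  })), , drop = FALSE]
}

#' Rebuild a PLSR model on selected wavelengths
#'
#' Maps each selected wavelength to the nearest grid column (tolerance:
#' half the local grid pitch, so an off-grid request like 1191 nm lands
#' on its neighbour on a 3.6 nm grid), refits PLSR on those columns with
#' the LV count re-chosen by LOOCV on the calibration rows, and returns
#' the full metric set.
#'
#' @param pre preprocessed [SpectraSet-class] (same transform as the
#'   parent full-spectrum model).
#' @param refs a [ReferenceTable-class].
#' @param trait trait name.
#' @param selection a [SelectionResult-class] (or numeric wavelengths).
#' @param split a [randomSplit()] result.
#' @param aMax LOOCV component cap.
#' @return List with `report` (one-row data.frame as in
#'   [screenPreprocessings()] plus `nWavelengths`), `model` (the
#'   [PLSRModel-class]) and `columns` (mapped column indices).
#' @export
buildMultispectralModel <- function(pre, refs, trait, selection, split,
                                    aMax = 15L) {
  nm <- if (is(selection, "SelectionResult")) {
    selectedWavelengths(selection)
  } else {
    as.numeric(selection)
  }
  if (!length(nm)) stop("empty wavelength selection")
  grid <- wavelengths(pre)
  idx <- vapply(nm, function(w) which.min(abs(grid - w)), integer(1L))
  pitch <- diff(grid)
  halfLocal <- vapply(idx, function(i) {
    gaps <- pitch[c(max(i - 1L, 1L), min(i, length(pitch)))]
    min(gaps) / 2
  }, numeric(1L))
  off <- abs(grid[idx] - nm) > halfLocal + 1e-9
  if (any(off)) {
    stop(
      "wavelength(s) farther than half a pitch from the grid: ",
      paste(nm[off], collapse = ", ")
    )
  }
  idx <- sort(unique(idx))
  sub <- pre[, idx]
  cell <- evaluateCell(sub, refs, split, trait, "selected", aMax)
  calIdx <- match(split$calibrationIds, sampleIds(sub))
  y <- traitValues(refs, trait)[match(sampleIds(sub), sampleIds(refs))]
  model <- fitPLSR(
    intensities(sub)[calIdx, , drop = FALSE], y[calIdx],
    cell$nLV,
    wavelengths = wavelengths(sub)
  )
  report <- as.data.frame(cell)
  report$nWavelengths <- length(idx)
  list(report = report, model = model, columns = idx)
}

#' Configuration for the full analysis
#'
#' @param sim a [simConfig()] for the synthetic fixture (ignored when
#'   `spectraList`/`refs` are supplied to [runFullAnalysis()]).
#' @param seed master seed; stage seeds are derived from it (traits
#'   seed, spectra seed + 1, split seed + 2, random frog seed + 3).
#' @param nCal calibration-set size (study design: 70 of 97).
#' @param aMax LOOCV component cap.
#' @param rpdGate traits advance to wavelength selection only when their
#'   optimal full-spectrum model reaches this RPD (default 1.5, the
#'   inadequacy threshold).
#' @param nSelRC named vector of RC selection sizes per trait (defaults:
#'   7 for fat, 8 otherwise).
#' @param nSelRF random-frog selection size (default 10).
#' @param rf an [rfParams()].
#' @return An `AnalysisConfig` list.
#' @export
analysisConfig <- function(sim = simConfig(), seed = 7L, nCal = 70L,
                           aMax = 15L, rpdGate = 1.5,
                           nSelRC = c(
                             fat = 7L, protein = 8L, collagen = 8L,
                             ash = 8L, Na = 8L
                           ),
                           nSelRF = 10L, rf = rfParams()) {
  structure(
    list(
      sim = sim, seed = as.integer(seed), nCal = as.integer(nCal),
      aMax = as.integer(aMax), rpdGate = rpdGate, nSelRC = nSelRC,
      nSelRF = as.integer(nSelRF), rf = rf
    ),
    class = "AnalysisConfig"
  )
}

#' Run the full dual-band calibration experiment
#'
#' Orchestrates the whole study design: simulate (unless data are
#' supplied) -> trim noise bands -> descriptive statistics and trait
#' correlations -> preprocessing screening over both bands ->
#' RPD-gated wavelength selection (RC and random frog) on the optimal
#' full-spectrum model -> multispectral model rebuilding -> report
#' emission. Fully deterministic under the config seed. Reports are
#' written as five CSVs (`descriptive_stats.csv`,
#' `trait_correlations.csv`, `screening.csv`, `selected_wavelengths.csv`,
#' `multispectral.csv`) plus `run_log.txt` when `outDir` is given.
#'
#' @param config an [analysisConfig()].
#' @param outDir optional report directory.
#' @param spectraList optional named list of [SpectraSet-class] objects
#'   (else the synthetic generator is used).
#' @param refs optional [ReferenceTable-class] matching `spectraList`.
#' @return Invisible list: `refs`, `spectraList`, `split`, `stats`,
#'   `correlations`, `screening`, `optimal`, `gatedTraits`, `selections`,
#'   `multispectral`, `files`.
#' @export
runFullAnalysis <- function(config = analysisConfig(), outDir = NULL,
                            spectraList = NULL, refs = NULL) {
  log <- character()
  note <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }
  if (is.null(spectraList) || is.null(refs)) {
    refs <- drawReferenceTraits(config$sim, config$seed)
    raw <- renderSpectra(
      refs, componentBandLibrary(), config$sim, config$seed + 1L
    )
    spectraList <- list(VNIR = raw$vnir, NIR = raw$nir)
    note("simulated %d samples", nSamples(refs))
  }
  spectraList <- list(
    VNIR = trimNoiseBands(spectraList$VNIR, defaultBandSpec("VNIR")),
    NIR = trimNoiseBands(spectraList$NIR, defaultBandSpec("NIR"))
  )
  split <- randomSplit(sampleIds(refs), config$nCal, config$seed + 2L)
  note(
    "split: %d calibration / %d prediction",
    length(split$calibrationIds), length(split$predictionIds)
  )

  statsTab <- do.call(rbind, lapply(traitNames(refs), function(tr) {
    do.call(rbind, lapply(
      c(calibration = "calibrationIds", prediction = "predictionIds"),
      function(f) {
        d <- descriptiveStats(
          traitValues(refs, tr)[match(split[[f]], sampleIds(refs))]
        )
        data.frame(
          trait = tr,
          subset = if (f == "calibrationIds") "calibration" else "prediction",
          mean = d$mean, sd = d$sd, min = d$min, max = d$max,
          cvPercent = d$cvPercent
        )
      }
    ))
  }))
  rownames(statsTab) <- NULL

  pm <- pearsonMatrix(refs)
  corTab <- data.frame(
    trait1 = rep(rownames(pm$r), ncol(pm$r)),
    trait2 = rep(colnames(pm$r), each = nrow(pm$r)),
    r = as.vector(pm$r), flag = as.vector(pm$flags)
  )

  screening <- screenPreprocessings(
    spectraList, refs, split,
    aMax = config$aMax
  )
  best <- optimalCells(screening)
  note(
    "screening: %d cells, %d failed", nrow(screening),
    sum(!is.na(screening$error))
  )

  gated <- best$trait[best$rpd >= config$rpdGate]
  note(
    "RPD gate %.2f passed by: %s", config$rpdGate,
    paste(sort(gated), collapse = ", ")
  )

  selections <- list()
  msRows <- list()
  selTab <- data.frame()
  for (trait in gated) {
    cell <- best[best$trait == trait, ]
    pre <- applyPreprocessing(
      spectraList[[cell$band]], as.character(cell$preprocessing)
    )
    calIdx <- match(split$calibrationIds, sampleIds(pre))
    y <- traitValues(refs, trait)[match(sampleIds(pre), sampleIds(refs))]
    xc <- intensities(pre)[calIdx, , drop = FALSE]
    parent <- fitPLSR(xc, y[calIdx], cell$nLV,
      wavelengths = wavelengths(pre)
    )
    nRC <- if (trait %in% names(config$nSelRC)) {
      config$nSelRC[[trait]]
    } else {
      8L
    }
    sel <- list(
      RC = selectByRC(parent, nRC),
      RF = randomFrog(
        xc, y[calIdx], wavelengths(pre), config$rf, config$nSelRF,
        seed = config$seed + 3L
      )
    )
    selections[[trait]] <- sel
    for (method in names(sel)) {
      s <- sel[[method]]
      selTab <- rbind(selTab, data.frame(
        trait = trait, method = method,
        wavelength = selectedWavelengths(s),
        importance = selectionImportance(s)
      ))
      ms <- buildMultispectralModel(pre, refs, trait, s, split,
        aMax = config$aMax
      )
      row <- ms$report
      row$trait <- trait
      row$method <- method
      row$band <- cell$band
      row$preprocessing <- cell$preprocessing
      msRows[[paste(trait, method)]] <- row
      note(
        "%s/%s multispectral: %d wavelengths, Rp = %.3f, RPD = %.3f",
        trait, method, row$nWavelengths, row$rP, row$rpd
      )
    }
  }
  multispectral <- if (length(msRows)) {
    do.call(rbind, msRows)
  } else {
    data.frame()
  }
  rownames(multispectral) <- NULL

  files <- NULL
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    files <- c(
      descriptive_stats = file.path(outDir, "descriptive_stats.csv"),
      trait_correlations = file.path(outDir, "trait_correlations.csv"),
      screening = file.path(outDir, "screening.csv"),
      selected_wavelengths = file.path(outDir, "selected_wavelengths.csv"),
      multispectral = file.path(outDir, "multispectral.csv")
    )
    utils::write.csv(roundReport(statsTab), files[["descriptive_stats"]],
      row.names = FALSE
    )
    utils::write.csv(roundReport(corTab), files[["trait_correlations"]],
      row.names = FALSE
    )
    utils::write.csv(roundReport(screening), files[["screening"]],
      row.names = FALSE
    )
    utils::write.csv(roundReport(selTab), files[["selected_wavelengths"]],
      row.names = FALSE
    )
    utils::write.csv(roundReport(multispectral), files[["multispectral"]],
      row.names = FALSE
    )
    writeLines(log, file.path(outDir, "run_log.txt"))
  }

  invisible(list(
    refs = refs, spectraList = spectraList, split = split,
    stats = statsTab, correlations = corTab, screening = screening,
    optimal = best, gatedTraits = sort(gated), selections = selections,
    multispectral = multispectral, files = files, log = log
  ))
}

# Report rounding convention: three decimals for model metrics and
# correlations, one for CV%.
roundReport <- function(df) {
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    df[[nm]] <- if (nm == "cvPercent") {
      round(df[[nm]], 1L)
    } else {
      round(df[[nm]], 3L)
    }
  }
  df
}
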