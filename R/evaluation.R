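#' Correlation and RMSE between reference and predicted values
#'
#' R is the Pearson correlation of reference and prediction; RMSE is the
#' root mean squared error with denominator n (same units as y, g/kg for
#' the study traits).
#'
#' @param yRef numeric reference values (non-constant).
#' @param yPred numeric predictions, same length.
#' @return Named list `list(r, rmse)`.
#' @export
regressionMetrics <- function(yRef, yPred) {
  if (length(yRef) != length(yPred)) stop("length mismatch")
  if (length(yRef) < 2L) stop("need at least 2 values")
  if (stats::sd(yRef) == 0) stop("constant reference values: R undefined")
  list(
    r = stats::cor(yRef, yPred),
    rmse = sqrt(mean((yRef - yPred)^2))
  )
}

#' Residual predictive deviation
#'
#' RPD = SD of the prediction-set reference values divided by RMSEP
#' (dimensionless). Interpretation bands: below 1.5 the prediction is
#' inadequate; at least 2.5 is good for calibration; 5 or more is
#' adequate for analytical purposes.
#'
#' @param sdPredictionSet standard deviation (n-1) of the prediction-set
#'   reference values; must be positive.
#' @param rmsep root mean squared error of prediction; must be positive.
#' @return List `list(rpd, label)` where label is one of `"inadequate"`,
#'   `"screening"`, `"good"`, `"analytical"`.
#' @export
rpd <- function(sdPredictionSet, rmsep) {
  if (sdPredictionSet <= 0 || rmsep <= 0) {
    stop("sd and rmsep must be positive")
  }
  value <- sdPredictionSet / rmsep
  label <- if (value < 1.5) {
    "inadequate"
  } else if (value < 2.5) {
    "screening"
  } else if (value < 5) {
    "good"
  } else {
    "analytical"
  }
  list(rpd = value, label = label)
}

#' Descriptive statistics for a trait vector
#'
#' Mean, SD (n-1), range and coefficient of variation
#' `CV% = 100 * sd / mean` (reported to one decimal).
#'
#' @param values numeric vector, length >= 2.
#' @return List `list(mean, sd, min, max, cvPercent)`; `cvPercent` is
#'   rounded to one decimal.
#' @export
descriptiveStats <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  list(
    mean = m, sd = s, min = min(values), max = max(values),
    cvPercent = round(100 * s / m, 1L)
  )
}

#' Pairwise Pearson correlations of the reference traits
#'
#' Two-sided significance from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom;
#' flags `**` for p < 0.01 and `*` for p < 0.05. A constant trait yields
#' NA entries (correlation undefined).
#'
#' @param refs a [ReferenceTable-class] with at least 3 samples.
#' @return List with numeric matrix `r`, matrix `p`, and character matrix
#'   `flags` (`""`, `"*"` or `"**"`).
#' @export
pearsonMatrix <- function(refs) {
  tr <- refs@traits
  n <- nrow(tr)
  if (n < 3L) stop("need at least 3 samples")
  k <- ncol(tr)
  const <- apply(tr, 2L, function(v) stats::sd(v) == 0)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(tr), colnames(tr)))
  pv <- r
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (const[i] || const[j]) next
      rij <- stats::cor(tr[, i], tr[, j])
      r[i, j] <- rij
      if (i == j) {
        pv[i, j] <- 0
      } else {
        tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
        pv[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
      }
    }
  }
  flags <- matrix("", k, k, dimnames = dimnames(r))
  flags[!is.na(pv) & pv < 0.05] <- "*"
  flags[!is.na(pv) & pv < 0.01] <- "**"
  diag(flags) <- ""
  list(r = r, p = pv, flags = flags)
}

#' Random calibration/prediction split
#'
#' Uniform partition of the sample ids without replacement, deterministic
#' under the seed. The reference design is 70 calibration and 27 prediction
#' samples out of 97.
#'
#' @param ids character vector of sample ids.
#' @param nCal calibration-set size, below `length(ids)`.
#' @param seed integer RNG seed.
#' @return List `list(calibrationIds, predictionIds, seed)`.
#' @export
randomSplit <- function(ids, nCal, seed) {
  n <- length(ids)
  if (nCal >= n) stop("nCal must be smaller than the number of samples")
  if (nCal < 1L) stop("nCal must be positive")
  rng <- local({
    set.seed(seed)
    sample.int(n, nCal)
  })
  list(
    calibrationIds = ids[sort(rng)],
    predictionIds = ids[-sort(rng)],
    seed = as.integer(seed)
  )
}
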