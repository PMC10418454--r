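#' Fit a PLSR model by NIPALS
#'
#' Single-response partial least squares regression. `X` and `y` are
#' mean-centred; each component takes the weight `w` proportional to
#' `X'y` (unit norm), score `t = Xw`, x-loading `p = X't / t't`,
#' y-loading `q = y't / t't`, then deflates `X <- X - t p'` and
#' `y <- y - q t`. The regression vector is assembled as
#' `beta = W (P'W)^{-1} q` and folded back to the raw scale with an
#' intercept, so `predict()` is a plain affine map.
#'
#' @param X numeric n x p predictor matrix (n >= 3, not all-constant).
#' @param y numeric response vector, length n.
#' @param nLV number of latent variables, `1 <= nLV <= min(n - 1, p)`.
#' @param wavelengths optional numeric grid attached to the model (used
#'   by wavelength selection).
#' @return A [PLSRModel-class].
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X[, 1] + rnorm(20, sd = 0.1)
#' m <- fitPLSR(X, y, 2)
#' @export
fitPLSR <- function(X, y, nLV, wavelengths = numeric()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3L) stop("need at least 3 samples")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > min(n - 1L, p)) {
    stop("nLV must lie in [1, min(n - 1, p)]")
  }
  if (all(apply(X, 2L, function(c) max(c) - min(c)) == 0)) {
    stop("all X columns constant")
  }
  fit <- cpp_pls_fit(X, y, nLV)
  if (fit$ncomp < nLV) {
    stop(sprintf(
      "rank deficiency: response orthogonal to residual X at component %d",
      fit$ncomp + 1L
    ))
  }
  beta <- as.numeric(fit$B[, nLV])
  new("PLSRModel",
    xMean = as.numeric(fit$xmean), yMean = fit$ymean,
    weights = fit$W, xLoadings = fit$P, yLoadings = as.numeric(fit$q),
    scores = fit$T, nLV = nLV, beta = beta,
    intercept = fit$ymean - sum(as.numeric(fit$xmean) * beta),
    wavelengths = as.numeric(wavelengths)
  )
}

#' Predict from a PLSRModel
#'
#' @param object a [PLSRModel-class].
#' @param newdata numeric matrix with the same column count the model was
#'   fitted on.
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@beta)) {
    stop(sprintf(
      "newdata has %d columns; model expects %d",
      ncol(newdata), length(object@beta)
    ))
  }
  as.numeric(newdata %*% object@beta) + object@intercept
})

#' Regression coefficient vector of a PLSRModel
#'
#' @param object a [PLSRModel-class].
#' @param ... ignored.
#' @return Numeric p-vector of raw-scale coefficients (no intercept).
#' @export
setMethod("coef", "PLSRModel", function(object, ...) object@beta)

#' Choose the latent-variable count by leave-one-out cross-validation
#'
#' For each left-out sample the model is refitted on the remaining
#' `n - 1` rows (centring recomputed inside the fold) and the held-out
#' sample predicted at every component count up to `aMax`. The optimal LV
#' count minimises RMSECV, ties broken toward the smaller count. If some
#' fold runs rank-deficient before `aMax` components the curve is
#' truncated there with a warning.
#'
#' @param X numeric n x p matrix (n >= 4).
#' @param y numeric response.
#' @param aMax largest component count to consider,
#'   `aMax <= min(n - 2, p)`.
#' @return A [CVResult-class].
#' @export
loocvSelectLV <- function(X, y, aMax = 15L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4L) stop("LOOCV needs at least 4 samples")
  aMax <- as.integer(min(aMax, n - 2L, ncol(X)))
  cv <- cpp_pls_loocv(X, y, aMax)
  amin <- cv$amin
  if (amin < 1L) stop("rank deficiency: no component extractable in some fold")
  truncated <- amin < aMax
  if (truncated) {
    warning(sprintf(
      "RMSECV curve truncated at %d components (rank deficiency)", amin
    ))
  }
  preds <- cv$preds[, seq_len(amin), drop = FALSE]
  rmsecv <- sqrt(colMeans((preds - y)^2))
  opt <- which.min(rmsecv) # which.min takes the first minimum: smallest LV
  new("CVResult",
    rmsecvByLV = as.numeric(rmsecv), optimalLV = as.integer(opt),
    rCv = stats::cor(preds[, opt], y), predictions = preds,
    truncated = truncated
  )
}
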