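#' Select wavelengths at regression-coefficient extrema
#'
#' Informative wavelengths sit at the peaks and valleys of the PLSR
#' regression-coefficient curve. Interior local extrema of `beta` over
#' the wavelength index are located sign-aware (maxima with positive
#' curvature neighbours, minima likewise), ranked by absolute
#' coefficient, and the top `nSel` returned sorted by wavelength. The
#' ranking is invariant to multiplying `beta` by any positive constant.
#'
#' @param model a [PLSRModel-class] fitted with a wavelength grid.
#' @param nSel number of wavelengths to select (>= 1).
#' @return A [SelectionResult-class] with method `"RC"`; if the curve has
#'   fewer extrema than `nSel`, all extrema are returned and the
#'   `shortfall` flag set.
#' @export
selectByRC <- function(model, nSel) {
  grid <- model@wavelengths
  if (!length(grid)) stop("model carries no wavelength grid")
  nSel <- as.integer(nSel)
  if (nSel < 1L) stop("nSel must be >= 1")
  beta <- model@beta
  p <- length(beta)
  if (p < 3L) stop("need at least 3 wavelengths to find interior extrema")
  i <- 2:(p - 1L)
  isMax <- beta[i] > beta[i - 1L] & beta[i] > beta[i + 1L]
  isMin <- beta[i] < beta[i - 1L] & beta[i] < beta[i + 1L]
  ext <- i[isMax | isMin]
  shortfall <- length(ext) < nSel
  take <- ext[order(abs(beta[ext]), decreasing = TRUE)]
  take <- take[seq_len(min(nSel, length(take)))]
  ord <- order(grid[take])
  new("SelectionResult",
    method = "RC", selectedNm = grid[take][ord],
    importance = abs(beta[take])[ord], nRequested = nSel,
    seed = NA_real_, shortfall = shortfall
  )
}

#' Random frog parameters
#'
#' Tuning constants for the reversible-jump subset sampler: the chain
#' proposes a new subset size from a normal centred on the current size
#' (spread `theta`), shrinks by keeping the largest-coefficient members
#' or grows by sampling `omega` times the deficit from outside the
#' subset, and accepts worse candidates with probability damped by
#' `eta` times the RMSECV ratio.
#'
#' @param nIterations chain length N (default 1000).
#' @param qInit initial subset size.
#' @param theta candidate-size spread factor (sd of the proposal is
#'   `theta * q`).
#' @param omega oversampling multiplier for growth moves.
#' @param eta acceptance damping for worse candidates, in (0, 1].
#' @param maxLVSubmodel cap on submodel latent variables.
#' @return An `RFParams` list.
#' @export
rfParams <- function(nIterations = 1000L, qInit = 10L, theta = 0.3,
                     omega = 3, eta = 0.1, maxLVSubmodel = 5L) {
  if (nIterations < 1L) stop("nIterations must be >= 1")
  if (qInit < 1L) stop("qInit must be >= 1")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  structure(
    list(
      nIterations = as.integer(nIterations), qInit = as.integer(qInit),
      theta = theta, omega = omega, eta = eta,
      maxLVSubmodel = as.integer(maxLVSubmodel)
    ),
    class = "RFParams"
  )
}

# LOOCV RMSECV of a PLSR submodel on columns `cols`, LV count chosen by
# the submodel's own LOOCV up to the cap. Returns Inf on rank failure.
rfSubmodelScore <- function(X, y, cols, maxLV) {
  aMax <- min(maxLV, length(cols) - 1L, nrow(X) - 2L)
  if (aMax < 1L) aMax <- 1L
  cv <- tryCatch(
    suppressWarnings(cpp_pls_loocv(X[, cols, drop = FALSE], y, aMax)),
    error = function(e) NULL
  )
  if (is.null(cv) || cv$amin < 1L) {
    return(list(score = Inf, lv = 0L))
  }
  preds <- cv$preds[, seq_len(cv$amin), drop = FALSE]
  rmsecv <- sqrt(colMeans((preds - y)^2))
  a <- which.min(rmsecv)
  list(score = rmsecv[a], lv = a)
}

# |beta| ranking of columns `cols` using a submodel at the LOOCV-chosen
# LV count (capped). Returns cols ordered by decreasing importance.
rfRankByBeta <- function(X, y, cols, maxLV) {
  sc <- rfSubmodelScore(X, y, cols, maxLV)
  if (!is.finite(sc$score)) {
    return(NULL)
  }
  fit <- tryCatch(
    cpp_pls_fit(X[, cols, drop = FALSE], y, sc$lv),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$ncomp < 1L) {
    return(NULL)
  }
  beta <- abs(fit$B[, min(sc$lv, fit$ncomp)])
  cols[order(beta, decreasing = TRUE)]
}

#' Random frog wavelength selection
#'
#' Reversible-jump MCMC-style subset sampler. Each of the N iterations
#' draws a candidate subset size `q*` from `round(Normal(q, theta * q))`
#' clipped to `[1, p]`. If `q* <= q` the current subset is shrunk to its
#' `q*` largest-|beta| members (beta from a PLSR submodel); if `q* > q`,
#' `min(omega * (q* - q), p - q)` outside variables are drawn uniformly,
#' a submodel is fitted on the union and the top `q*` by |beta| kept. The
#' candidate is accepted when its LOOCV RMSECV does not exceed the
#' current one, otherwise with probability
#' `eta * RMSECV_current / RMSECV_candidate`. The selection probability
#' of a wavelength is the fraction of iterations whose accepted subset
#' contained it; the `nSel` most probable wavelengths are returned.
#' Candidates whose submodel is rank-degenerate are rejected.
#'
#' @param X numeric n x p calibration matrix; prediction samples must be
#'   excluded by the caller — selection never sees them.
#' @param y numeric calibration response.
#' @param grid numeric wavelength grid, length p.
#' @param params an [rfParams()].
#' @param nSel number of wavelengths to return (default 10).
#' @param seed integer seed; the run is bit-reproducible under it.
#' @return A [SelectionResult-class] with method `"RF"`; its
#'   `selectionImportance` are the selection probabilities of the chosen
#'   wavelengths. The full probability vector is attached as attribute
#'   `"probabilities"`.
#' @export
randomFrog <- function(X, y, grid, params = rfParams(), nSel = 10L,
                       seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  if (length(grid) != p) stop("grid length must equal ncol(X)")
  if (p < params$qInit) stop("qInit exceeds the number of wavelengths")
  if (nrow(X) < 6L) stop("random frog needs at least 6 samples")
  set.seed(as.integer(seed))
  maxLV <- params$maxLVSubmodel
  current <- sort(sample.int(p, params$qInit))
  curScore <- rfSubmodelScore(X, y, current, maxLV)$score
  hits <- numeric(p)
  for (it in seq_len(params$nIterations)) {
    q <- length(current)
    qStar <- as.integer(round(stats::rnorm(1L, q, params$theta * q)))
    qStar <- max(1L, min(p, qStar))
    if (qStar <= q) {
      if (qStar == q) {
        candidate <- current
      } else {
        ranked <- rfRankByBeta(X, y, current, maxLV)
        candidate <- if (is.null(ranked)) NULL else sort(ranked[seq_len(qStar)])
      }
    } else {
      outside <- setdiff(seq_len(p), current)
      nDraw <- min(ceiling(params$omega * (qStar - q)), length(outside))
      pool <- sort(c(current, sample(outside, nDraw)))
      ranked <- rfRankByBeta(X, y, pool, maxLV)
      candidate <- if (is.null(ranked)) NULL else sort(ranked[seq_len(qStar)])
    }
    if (!is.null(candidate)) {
      candScore <- rfSubmodelScore(X, y, candidate, maxLV)$score
      accept <- if (!is.finite(candScore)) {
        FALSE
      } else if (candScore <= curScore) {
        TRUE
      } else {
        stats::runif(1L) < params$eta * (curScore / candScore)
      }
      if (accept) {
        current <- candidate
        curScore <- candScore
      }
    }
    hits[current] <- hits[current] + 1
  }
  prob <- hits / params$nIterations
  take <- order(prob, decreasing = TRUE)[seq_len(min(nSel, p))]
  ord <- order(grid[take])
  res <- new("SelectionResult",
    method = "RF", selectedNm = grid[take][ord],
    importance = prob[take][ord], nRequested = as.integer(nSel),
    seed = as.numeric(seed), shortfall = length(take) < nSel
  )
  attr(res, "probabilities") <- prob
  res
}
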