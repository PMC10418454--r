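# Shared fixture builders. Everything is generated in code at test time.

# tiny spectra container on an arbitrary grid
makeSpectra <- function(m, wl = NULL, band = "NIR", ids = NULL) {
  m <- rbind(m)
  if (is.null(wl)) wl <- seq(1000, by = 2, length.out = ncol(m))
  SpectraSet(wl, m, band, ids)
}

# smooth spectrum: sum of broad Gaussians (widths >= 120 nm so that
# window-scale filter effects stay below the oracle tolerances)
smoothRow <- function(wl, seed, nBands = 5, widths = c(120, 160)) {
  set.seed(seed)
  ctr <- stats::runif(nBands, min(wl), max(wl))
  wd <- stats::runif(nBands, widths[1], widths[2])
  am <- stats::runif(nBands, 0.2, 1)
  colSums(am * exp(-outer(ctr, wl, `-`)^2 / (2 * wd^2)))
}

# regression problem with 5 planted informative columns (SNR 10)
plantedColumns <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  truth <- round(seq(0.1, 0.9, length.out = 5) * p)
  b <- c(1, -1, 1, 1, -1)
  sig <- as.numeric(X[, truth, drop = FALSE] %*% b)
  y <- sig + stats::rnorm(n, sd = sqrt(stats::var(sig) / 10))
  list(X = X, y = y, truth = truth)
}

# independent R-level NIPALS (oracle for the compiled core)
rNipals <- function(X, y, A) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    pv <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - outer(t, pv)
    yc <- yc - qa * t
    W[, a] <- w
    P[, a] <- pv
    q[a] <- qa
  }
  beta <- W %*% solve(crossprod(P, W), q)
  list(beta = drop(beta), intercept = ym - sum(xm * beta))
}

# one full-analysis run on the default synthetic study design, shared
# across test files (the expensive end-to-end fixture)
.runCache <- new.env(parent = emptyenv())
defaultRun <- function() {
  if (is.null(.runCache$run)) {
    .runCache$run <- runFullAnalysis(analysisConfig(seed = 7))
  }
  .runCache$run
}
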