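#' Gaussian absorption-band library for the synthetic spectra
#'
#' Each organic component contributes a set of broad Gaussian bands
#' (centre, width, amplitude per g/kg) placed at the characteristic
#' wavelengths of the matrix: water at 771 nm (O-H third overtone),
#' 979 nm (O-H second overtone) and ~1450 nm; fat at 813 nm and 1220 nm
#' (C-H symmetric-stretch second overtone); protein at 872 nm, 1020 nm,
#' 1180 nm, 1423 nm (C-H combination) and 1510 nm (N-H first overtone).
#' Collagen shares the protein band positions at reduced amplitude, which
#' is why it is only weakly recoverable next to the larger protein
#' signal. The higher-overtone bands below 950 nm are an order of
#' magnitude weaker than their NIR counterparts, as overtone intensities
#' fall steeply with order. Ash and Na carry no bands: inorganic salts do
#' not absorb in the near infrared.
#'
#' @return Named list (`water`, `fat`, `protein`, `collagen`) of data
#'   frames with columns `center`, `width`, `amplitude`.
#' @export
componentBandLibrary <- function() {
  list(
    water = data.frame(
      center = c(771, 979, 1450),
      width = c(20, 35, 45),
      amplitude = c(1.6e-4, 9e-4, 8e-4)
    ),
    fat = data.frame(
      center = c(813, 1220),
      width = c(18, 25),
      amplitude = c(4e-4, 2.5e-3)
    ),
    protein = data.frame(
      center = c(872, 1020, 1180, 1423, 1510),
      width = c(18, 30, 30, 35, 40),
      amplitude = c(1.5e-4, 6e-4, 6e-4, 8e-4, 1.3e-3)
    ),
    collagen = data.frame(
      center = c(872, 1020, 1180, 1423, 1510),
      width = c(18, 30, 30, 35, 40),
      amplitude = 0.4 * c(1.5e-4, 6e-4, 6e-4, 8e-4, 1.3e-3)
    )
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 97 samples, the five-trait
#' distribution (calibration-set means/SDs/ranges in g/kg), an ash-Na
#' correlation near 0.77 and a collagen-protein correlation near 0.35,
#' dual instrument grids (650-949.8 nm at 0.35 nm pitch; 960-1660 nm at
#' 3.6 nm), and multiplicative/additive scatter, low-order baseline drift
#' and white noise on top of the clean Beer-Lambert-style mixture signal.
#'
#' @param nSamples number of samples (>= 10).
#' @param traits data frame with columns `mean`, `sd`, `min`, `max` and
#'   row names `fat`, `protein`, `collagen`, `ash`, `Na` (g/kg).
#' @param ashNaCorrelation target Pearson r between ash and Na (< 0.999).
#' @param collagenProteinCorrelation target r between collagen and
#'   protein.
#' @param scatterMultSd sd of the per-sample multiplicative scatter gain
#'   (gain ~ Normal(1, sd)).
#' @param scatterAddSd sd of the per-sample additive offset.
#' @param baselineLinearSd,baselineQuadSd sds of the per-sample linear
#'   (per nm) and quadratic (per nm^2) baseline drift coefficients.
#' @param noiseSd sd of i.i.d. measurement noise per channel.
#' @param waterTotal total mass budget (g/kg); water concentration is
#'   `waterTotal` minus the organic traits, floored at zero.
#' @param vnirGrid,nirGrid numeric wavelength grids for the two bands.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(nSamples = 97L,
                      traits = data.frame(
                        mean = c(51.2, 256.2, 26.1, 28.0, 8.5),
                        sd = c(33.2, 56.4, 18.6, 5.3, 2.4),
                        min = c(16.5, 146.5, 0.1, 12.0, 1.3),
                        max = c(162.5, 425.5, 104.0, 40.5, 16.2),
                        row.names = c(
                          "fat", "protein", "collagen", "ash", "Na"
                        )
                      ),
                      ashNaCorrelation = 0.77,
                      collagenProteinCorrelation = 0.35,
                      scatterMultSd = 0.08, scatterAddSd = 0.03,
                      baselineLinearSd = 1e-4, baselineQuadSd = 2e-7,
                      noiseSd = 0.05, waterTotal = 1000,
                      vnirGrid = seq(650, 949.8, by = 0.35),
                      nirGrid = seq(960, 1660, by = 3.6)) {
  if (nSamples < 10L) stop("nSamples must be >= 10")
  if (abs(ashNaCorrelation) > 0.999 ||
    abs(collagenProteinCorrelation) > 0.999) {
    stop("infeasible correlation target (|r| > 0.999)")
  }
  stopifnot(all(c("fat", "protein", "collagen", "ash", "Na")
  %in% rownames(traits)))
  structure(
    list(
      nSamples = as.integer(nSamples), traits = traits,
      ashNaCorrelation = ashNaCorrelation,
      collagenProteinCorrelation = collagenProteinCorrelation,
      scatterMultSd = scatterMultSd, scatterAddSd = scatterAddSd,
      baselineLinearSd = baselineLinearSd,
      baselineQuadSd = baselineQuadSd, noiseSd = noiseSd,
      waterTotal = waterTotal, vnirGrid = vnirGrid, nirGrid = nirGrid
    ),
    class = "SimConfig"
  )
}

# Underlying normal parameters whose [lower, upper]-truncated law has the
# requested mean and sd. Naive truncation of N(mean, sd) would inflate
# the mean whenever a range endpoint is close (the fat range cuts at
# z = -1.05), so the two moment equations are solved numerically. The
# mean is weighted heavily: when the family cannot reach the requested
# sd on the given range (the fat row), the mean is still matched and the
# closest achievable sd accepted.
truncNormParams <- function(mean, sd, lower, upper) {
  moments <- function(mu, sig) {
    a <- (lower - mu) / sig
    b <- (upper - mu) / sig
    z <- stats::pnorm(b) - stats::pnorm(a)
    dm <- (stats::dnorm(a) - stats::dnorm(b)) / z
    m <- mu + sig * dm
    v <- sig^2 *
      (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - dm^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) {
    mm <- moments(par[1L], exp(par[2L]))
    if (!all(is.finite(mm))) {
      return(1e10)
    }
    25 * ((mm[1L] - mean) / sd)^2 + ((mm[2L] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
    control = list(maxit = 5000, reltol = 1e-15)
  )
  got <- moments(fit$par[1L], exp(fit$par[2L]))
  if (abs(got[1L] - mean) > 0.02 * sd || abs(got[2L] - sd) > 0.25 * sd) {
    stop("cannot match trait mean/sd under range truncation")
  }
  list(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

# Inverse-CDF draw from a truncated normal; exact truncation,
# deterministic under the caller's RNG state.
rtruncnorm <- function(n, mu, sigma, lower, upper) {
  lo <- stats::pnorm(lower, mu, sigma)
  hi <- stats::pnorm(upper, mu, sigma)
  stats::qnorm(stats::runif(n, lo, hi), mu, sigma)
}

#' Draw reference trait values
#'
#' Fat, protein and ash are independent truncated normals whose
#' truncated-law moments match the configured means/SDs. Collagen is an
#' affine function of protein plus Gaussian noise (target correlation
#' `collagenProteinCorrelation`), and Na an affine function of ash
#' (target `ashNaCorrelation`); both are clipped to their configured
#' ranges. A trait with `sd = 0` is set identically to its mean.
#'
#' @param cfg a [simConfig()].
#' @param seed integer RNG seed.
#' @return A [ReferenceTable-class] with `nSamples` rows.
#' @export
drawReferenceTraits <- function(cfg, seed) {
  set.seed(as.integer(seed))
  tr <- cfg$traits
  n <- cfg$nSamples
  drawMarginal <- function(trait) {
    row <- tr[trait, ]
    if (row$sd == 0) {
      return(rep(row$mean, n))
    }
    par <- truncNormParams(row$mean, row$sd, row$min, row$max)
    rtruncnorm(n, par$mu, par$sigma, row$min, row$max)
  }
  drawChild <- function(parent, parentTrait, trait, r) {
    row <- tr[trait, ]
    prow <- tr[parentTrait, ]
    if (row$sd == 0) {
      return(rep(row$mean, n))
    }
    slope <- r * row$sd / prow$sd
    noise <- stats::rnorm(n, 0, row$sd * sqrt(1 - r^2))
    raw <- row$mean + slope * (parent - prow$mean) + noise
    pmin(pmax(raw, row$min), row$max)
  }
  fat <- drawMarginal("fat")
  protein <- drawMarginal("protein")
  ash <- drawMarginal("ash")
  collagen <- drawChild(
    protein, "protein", "collagen",
    cfg$collagenProteinCorrelation
  )
  na <- drawChild(ash, "ash", "Na", cfg$ashNaCorrelation)
  ReferenceTable(
    sprintf("S%03d", seq_len(n)),
    cbind(fat = fat, protein = protein, collagen = collagen, ash = ash,
      Na = na)
  )
}

# Component curves on a grid: rows = components, columns = wavelengths.
componentCurves <- function(lib, grid) {
  t(vapply(lib, function(bands) {
    colSums(bands$amplitude * exp(
      -outer(bands$center, grid, `-`)^2 / (2 * bands$width^2)
    ))
  }, numeric(length(grid))))
}

#' Render dual-band spectra from reference traits
#'
#' The clean signal is the Beer-Lambert-style mixture
#' `A(lambda) = sum_c conc_c * K_c(lambda)` over water, fat, protein and
#' collagen (water concentration = `waterTotal` minus the organics,
#' floored at 0; ash and Na do not absorb). The observed spectrum adds
#' per-sample multiplicative scatter `a ~ N(1, scatterMultSd)`, an
#' additive offset, linear and quadratic baseline drift about the band
#' centre, and i.i.d. channel noise — drawn independently for the two
#' instruments. Setting every scatter/noise sd to zero yields spectra
#' exactly linear in the trait concentrations.
#'
#' @param refs a [ReferenceTable-class].
#' @param lib a [componentBandLibrary()].
#' @param cfg a [simConfig()].
#' @param seed integer RNG seed.
#' @return List of two [SpectraSet-class] objects, `vnir` and `nir`.
#' @export
renderSpectra <- function(refs, lib, cfg, seed) {
  set.seed(as.integer(seed))
  n <- nSamples(refs)
  organics <- traitValues(refs, "fat") + traitValues(refs, "protein") +
    traitValues(refs, "collagen")
  conc <- cbind(
    water = pmax(cfg$waterTotal - organics, 0),
    fat = traitValues(refs, "fat"),
    protein = traitValues(refs, "protein"),
    collagen = traitValues(refs, "collagen")
  )
  renderBand <- function(grid, label) {
    K <- componentCurves(lib[colnames(conc)], grid)
    clean <- conc %*% K
    a <- stats::rnorm(n, 1, cfg$scatterMultSd)
    b <- stats::rnorm(n, 0, cfg$scatterAddSd)
    d1 <- stats::rnorm(n, 0, cfg$baselineLinearSd)
    d2 <- stats::rnorm(n, 0, cfg$baselineQuadSd)
    lam <- grid - mean(grid)
    obs <- a * clean + b +
      outer(d1, lam) + outer(d2, lam^2) +
      matrix(stats::rnorm(n * length(grid), 0, cfg$noiseSd), n)
    SpectraSet(grid, obs, label, sampleIds(refs))
  }
  list(
    vnir = renderBand(cfg$vnirGrid, "VNIR"),
    nir = renderBand(cfg$nirGrid, "NIR")
  )
}

#' Write a complete synthetic fixture to disk
#'
#' Generates reference traits and dual-band spectra and writes
#' `vnir.csv`, `nir.csv` and `reference.csv` into `dir`. Byte-identical
#' across runs with the same seed.
#'
#' @param cfg a [simConfig()].
#' @param seed integer RNG seed (traits use `seed`, spectra `seed + 1`).
#' @param dir output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
makeFixture <- function(cfg, seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  refs <- drawReferenceTraits(cfg, seed)
  spectra <- renderSpectra(refs, componentBandLibrary(), cfg, seed + 1L)
  paths <- c(
    vnir = file.path(dir, "vnir.csv"),
    nir = file.path(dir, "nir.csv"),
    reference = file.path(dir, "reference.csv")
  )
  writeSpectraCSV(spectra$vnir, paths[["vnir"]])
  writeSpectraCSV(spectra$nir, paths[["nir"]])
  writeReferenceCSV(refs, paths[["reference"]])
  invisible(paths)
}
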