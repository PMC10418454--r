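test_that("reference trait draws match the configured distributions", {
  cfg <- simConfig(nSamples = 5000)
  refs <- drawReferenceTraits(cfg, 42)
  fat <- traitValues(refs, "fat")
  expect_lt(abs(mean(fat) - 51.2), 1.5)
  r <- cor(traitValues(refs, "ash"), traitValues(refs, "Na"))
  expect_lt(abs(r - 0.77), 0.05)
  rpc <- cor(traitValues(refs, "protein"), traitValues(refs, "collagen"))
  expect_lt(abs(rpc - 0.35), 0.07)
  # range constraints hold exactly
  tr <- cfg$traits
  for (t in rownames(tr)) {
    v <- traitValues(refs, t)
    expect_gte(min(v), tr[t, "min"])
    expect_lte(max(v), tr[t, "max"])
  }
})

test_that("a zero-sd trait collapses to its mean and bad targets error", {
  cfg <- simConfig(nSamples = 20)
  cfg$traits["fat", "sd"] <- 0
  refs <- drawReferenceTraits(cfg, 1)
  expect_equal(traitValues(refs, "fat"), rep(51.2, 20))
  expect_error(simConfig(ashNaCorrelation = 0.9999), "infeasible")
})

cleanConfig <- function(n = 20) {
  simConfig(
    nSamples = n, scatterMultSd = 0, scatterAddSd = 0,
    baselineLinearSd = 0, baselineQuadSd = 0, noiseSd = 0
  )
}

test_that("clean-mode spectra are linear in trait concentrations", {
  cfg <- cleanConfig()
  refs <- drawReferenceTraits(cfg, 5)
  lib <- componentBandLibrary()
  sp <- renderSpectra(refs, lib, cfg, 6)

  # concentrations recoverable by least squares on the component curves.
  # collagen's curve is exactly 0.4x protein's (they share bands), so the
  # identifiable components are water, fat and protein + 0.4 collagen.
  for (band in c("vnir", "nir")) {
    grid <- wavelengths(sp[[band]])
    curves <- vapply(lib, function(b) {
      colSums(b$amplitude *
        exp(-outer(b$center, grid, `-`)^2 / (2 * b$width^2)))
    }, numeric(length(grid)))
    K <- rbind(
      water = curves[, "water"], fat = curves[, "fat"],
      proteinLike = curves[, "protein"]
    )
    conc <- cbind(
      water = pmax(1000 - traitValues(refs, "fat") -
        traitValues(refs, "protein") - traitValues(refs, "collagen"), 0),
      fat = traitValues(refs, "fat"),
      proteinLike = traitValues(refs, "protein") +
        0.4 * traitValues(refs, "collagen")
    )
    est <- t(qr.solve(t(K), t(intensities(sp[[band]]))))
    expect_lt(max(abs(est - conc)) / max(conc), 1e-6)
  }
})

test_that("single-component limit and linearity in fat hold", {
  cfg <- cleanConfig(10)
  base <- drawReferenceTraits(cfg, 3)
  lib <- componentBandLibrary()
  tr <- base@traits
  tr[, c("protein", "collagen", "ash", "Na")] <- 0
  one <- ReferenceTable(sampleIds(base), tr)
  sp1 <- renderSpectra(one, lib, cfg, 4)$nir
  grid <- wavelengths(sp1)
  fatCurve <- colSums(lib$fat$amplitude *
    exp(-outer(lib$fat$center, grid, `-`)^2 / (2 * lib$fat$width^2)))
  waterCurve <- colSums(lib$water$amplitude *
    exp(-outer(lib$water$center, grid, `-`)^2 / (2 * lib$water$width^2)))
  fat <- tr[, "fat"]
  expected <- outer(fat, fatCurve) + outer(pmax(1000 - fat, 0), waterCurve)
  expect_equal(unname(intensities(sp1)), expected, tolerance = 1e-10)

  # doubling fat doubles the fat-attributable signal
  tr2 <- tr
  tr2[, "fat"] <- 2 * tr[, "fat"]
  sp2 <- renderSpectra(ReferenceTable(sampleIds(base), tr2), lib, cfg, 4)$nir
  delta1 <- intensities(sp1) - outer(pmax(1000 - fat, 0), waterCurve)
  delta2 <- intensities(sp2) - outer(pmax(1000 - 2 * fat, 0), waterCurve)
  expect_equal(delta2, 2 * delta1, tolerance = 1e-10)
})

test_that("SNV undoes pure multiplicative/additive scatter", {
  cfg <- cleanConfig(15)
  cfgScatter <- cfg
  cfgScatter$scatterMultSd <- 0.1
  cfgScatter$scatterAddSd <- 0.05
  refs <- drawReferenceTraits(cfg, 8)
  lib <- componentBandLibrary()
  clean <- renderSpectra(refs, lib, cfg, 9)$nir
  dirty <- renderSpectra(refs, lib, cfgScatter, 9)$nir
  expect_equal(intensities(snv(dirty)), intensities(snv(clean)),
    tolerance = 1e-8
  )
})

test_that("fixture files are deterministic and correctly sized", {
  cfg <- simConfig(nSamples = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- makeFixture(cfg, 77, d1)
  p2 <- makeFixture(cfg, 77, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  vnir <- readSpectraCSV(p1[["vnir"]], "VNIR")
  nir <- readSpectraCSV(p1[["nir"]], "NIR")
  expect_equal(nSamples(vnir), 10L)
  expect_equal(nWavelengths(vnir), length(seq(650, 949.8, by = 0.35)))
  expect_equal(nWavelengths(nir), length(seq(960, 1660, by = 3.6)))
  expect_equal(nWavelengths(nir), 195L)
  refs <- readReferenceCSV(p1[["reference"]])
  expect_equal(nSamples(refs), 10L)
})
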