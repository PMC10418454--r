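test_that("spectral CSV reading validates, sorts and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,650.0,650.35,650.7", "a,1,2,3", "b,4,5,6"), tmp)
  s <- readSpectraCSV(tmp, "VNIR")
  expect_equal(nSamples(s), 2L)
  expect_equal(nWavelengths(s), 3L)
  expect_equal(wavelengths(s), c(650, 650.35, 650.7))
  expect_equal(unname(intensities(s)[2, ]), c(4, 5, 6))

  # out-of-order headers get sorted, values follow their wavelength
  writeLines(c("id,700,650", "a,10,20"), tmp)
  s2 <- readSpectraCSV(tmp, "VNIR")
  expect_equal(wavelengths(s2), c(650, 700))
  expect_equal(unname(intensities(s2)[1, ]), c(20, 10))

  # write -> read reproduces values
  set.seed(1)
  s3 <- makeSpectra(matrix(rnorm(40), 4), band = "NIR")
  writeSpectraCSV(s3, tmp)
  s4 <- readSpectraCSV(tmp, "NIR")
  expect_equal(intensities(s4), intensities(s3), tolerance = 1e-12)
  expect_equal(wavelengths(s4), wavelengths(s3), tolerance = 1e-12)
})

test_that("malformed spectral CSVs are rejected with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,650,wavelength", "a,1,2"), tmp)
  expect_error(readSpectraCSV(tmp, "VNIR"), "non-numeric wavelength")

  writeLines(c("id,650,651", "a,1,2", "a,3,4"), tmp)
  expect_error(readSpectraCSV(tmp, "VNIR"), "duplicate sample id")

  writeLines(c("id,650,651", "a,1,", "b,3,4"), tmp)
  expect_error(readSpectraCSV(tmp, "VNIR"), "'a'")
})

test_that("trimNoiseBands keeps closed intervals and is idempotent", {
  s <- makeSpectra(matrix(1, 1, 5), wl = c(640, 650, 700, 950, 955))
  tr <- trimNoiseBands(s, bandSpec(c(650, 950), "VNIR"))
  expect_equal(wavelengths(tr), c(650, 700, 950)) # endpoints included
  tr2 <- trimNoiseBands(tr, bandSpec(c(650, 950), "VNIR"))
  expect_equal(intensities(tr2), intensities(tr))

  # instrument grids: VNIR head 399.8-949.8 nm, NIR 942.7-1698.3 nm
  vnirRaw <- makeSpectra(matrix(0, 1, 1572), wl = 399.8 + 0.35 * 0:1571)
  v <- trimNoiseBands(vnirRaw, defaultBandSpec("VNIR"))
  expect_gte(min(wavelengths(v)), 650)
  expect_lte(max(wavelengths(v)), 950)
  expect_equal(max(wavelengths(v)), 949.65, tolerance = 1e-6)

  nirRaw <- makeSpectra(matrix(0, 1, 211), wl = 942.7 + 3.6 * 0:210)
  n <- trimNoiseBands(nirRaw, bandSpec(c(960, 1650), "NIR"))
  expect_gte(min(wavelengths(n)), 960)
  expect_lte(max(wavelengths(n)), 1650)

  expect_error(
    trimNoiseBands(s, bandSpec(c(2000, 2100), "NIR")),
    "empty band"
  )
})

test_that("replicate averaging is an arithmetic mean", {
  set.seed(7)
  wl <- seq(1000, by = 2, length.out = 5)
  reps <- lapply(1:9, function(i) makeSpectra(matrix(rnorm(20), 4), wl))

  # identical sets: idempotence
  same <- averageReplicates(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_equal(intensities(same), intensities(reps[[1]]))

  # elementwise mean of {0}, {2} is {1}
  z <- makeSpectra(matrix(0, 2, 5), wl)
  two <- makeSpectra(matrix(2, 2, 5), wl)
  expect_true(all(intensities(averageReplicates(list(z, two))) == 1))

  # 9 joint == hierarchical 3 positions x 3 repeats (associativity)
  joint <- averageReplicates(reps)
  posMeans <- lapply(list(1:3, 4:6, 7:9), function(i) {
    averageReplicates(reps[i])
  })
  hier <- averageReplicates(posMeans)
  expect_equal(intensities(joint), intensities(hier), tolerance = 1e-12)

  # permutation invariance
  shuf <- averageReplicates(reps[sample(9)])
  expect_equal(intensities(shuf), intensities(joint), tolerance = 1e-12)

  # mismatches rejected
  offGrid <- makeSpectra(matrix(0, 4, 5), wl + 1)
  expect_error(averageReplicates(list(reps[[1]], offGrid)), "grid")
  offIds <- makeSpectra(matrix(0, 4, 5), wl, ids = paste0("x", 1:4))
  expect_error(averageReplicates(list(reps[[1]], offIds)), "ids")
})

test_that("SpectraSet validity rejects broken objects", {
  expect_error(SpectraSet(c(650, 650), matrix(0, 1, 2), "VNIR"), "increasing")
  expect_error(SpectraSet(c(650, 700), matrix(c(1, NA), 1), "VNIR"), "finite")
  expect_error(
    SpectraSet(c(650, 700), matrix(0, 2, 2), "VNIR", c("a", "a")),
    "duplicate"
  )
  expect_error(SpectraSet(650, matrix(0, 1, 1), "midband"), "bandLabel")
})

test_that("reference table I/O and validity work", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  refs <- ReferenceTable(
    c("a", "b"),
    data.frame(
      fat = c(50, 60), protein = c(250, 260), collagen = c(20, 30),
      ash = c(28, 27), Na = c(8, 9)
    )
  )
  writeReferenceCSV(refs, tmp)
  back <- readReferenceCSV(tmp)
  expect_equal(traitValues(back, "fat"), c(50, 60))
  expect_equal(traitNames(back), traitNames(refs))
  expect_error(ReferenceTable("a", data.frame(fat = -1)), "negative")
})
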