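test_that("stack construction enforces its invariants", {
  b <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  expect_s4_class(spectralStack(b, c(450, 540, 630)), "SpectralStack")
  expect_error(spectralStack(b, c(450, 540)), "wavelength count")
  expect_error(spectralStack(b, c(630, 540, 450)), "strictly increasing")
  expect_error(spectralStack(b * 2, c(450, 540, 630)), "\\[0, 1\\]")
})

test_that("per-band files round-trip through disk with sidecar metadata", {
  sc <- smallScene(rngSeed = 3, nSeeds = 4, imageSize = 128)
  d <- withr::local_tempdir()
  writeStack(sc$stack, d, bitsPerSample = 16)
  expect_true(file.exists(file.path(d, "synthetic-3.json")))
  st <- readStack(d)
  expect_equal(wavelengths(st), wavelengths(sc$stack))
  expect_equal(dishId(st), dishId(sc$stack))
  # 16-bit quantization error only
  expect_lt(max(abs(bands(st) - bands(sc$stack))), 1 / 65535 + 1e-9)
  side <- jsonlite::read_json(file.path(d, "synthetic-3.json"),
                              simplifyVector = TRUE)
  expect_equal(side$wavelengths_nm, canonicalWavelengths())
})

test_that("integer encodings are normalized by their max representable value", {
  d <- withr::local_tempdir()
  # 1x1 white 8-bit image reads as exactly 1.0
  tiff::writeTIFF(matrix(1, 1, 1), file.path(d, "w_365nm.tif"),
                  bits.per.sample = 8)
  st <- readStack(file.path(d, "w_365nm.tif"), wavelengths = 365)
  expect_identical(dim(bands(st)), c(1L, 1L, 1L))
  expect_equal(bands(st)[1, 1, 1], 1.0)
  # 8-bit and 16-bit encodings of one scene agree within 1/255
  sc <- smallScene(rngSeed = 5, nSeeds = 3, imageSize = 96)
  d8 <- withr::local_tempdir(); d16 <- withr::local_tempdir()
  writeStack(sc$stack, d8, bitsPerSample = 8)
  writeStack(sc$stack, d16, bitsPerSample = 16)
  s8 <- readStack(d8); s16 <- readStack(d16)
  expect_lt(max(abs(bands(s8) - bands(s16))), 1 / 255)
})

test_that("dimension mismatches are reported with the offending file", {
  d <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.5, 8, 8), file.path(d, "a_365nm.tif"))
  tiff::writeTIFF(matrix(0.5, 9, 8), file.path(d, "a_405nm.tif"))
  expect_error(readStack(d), "a_405nm")
})

test_that("channel merge appends RGB after ascending bands and is invertible", {
  sc <- smallScene(rngSeed = 2, nSeeds = 2, imageSize = 96)
  cube <- mergeChannels(sc$stack)
  B <- nBands(sc$stack)
  expect_identical(dim(cubeArray(cube))[3], B + 3L)
  expect_identical(
    channelNames(cube),
    c(sprintf("%gnm", wavelengths(sc$stack)), "R", "G", "B"))
  # merge then split is the identity on band data
  expect_identical(cubeArray(cube)[, , seq_len(B)], bands(sc$stack))
  expect_identical(cubeArray(cube)[, , B + 1:3], rgbImage(sc$stack))
  # single-band stack gives C = 4
  one <- spectralStack(array(0.5, dim = c(4, 4, 1)), 660)
  expect_identical(dim(cubeArray(mergeChannels(one)))[3], 4L)
})

test_that("mean spectrum averages masked pixels and is linear in the mask", {
  b <- array(0.4, dim = c(6, 6, 2))
  st <- spectralStack(b, c(450, 850))
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  expect_equal(unname(meanSpectrum(st, m)), c(0.4, 0.4))
  # two-pixel mask with values 0.2 / 0.6 averages to 0.4
  b2 <- b; b2[1, 1, ] <- 0.2; b2[1, 2, ] <- 0.6
  st2 <- spectralStack(b2, c(450, 850))
  m2 <- matrix(FALSE, 6, 6); m2[1, 1:2] <- TRUE
  expect_equal(unname(meanSpectrum(st2, m2)), c(0.4, 0.4))
  # convex mixture: mean over a union is the pixel-weighted mixture
  mA <- matrix(FALSE, 6, 6); mA[4, ] <- TRUE
  mB <- matrix(FALSE, 6, 6); mB[5:6, ] <- TRUE
  stR <- spectralStack(array(runif(6 * 6 * 3), dim = c(6, 6, 3)),
                       c(1, 2, 3))
  wA <- sum(mA) / sum(mA | mB)
  expect_equal(meanSpectrum(stR, mA | mB),
               wA * meanSpectrum(stR, mA) + (1 - wA) * meanSpectrum(stR, mB))
  expect_error(meanSpectrum(st, matrix(FALSE, 6, 6)), "empty")
})

test_that("aged seeds reflect more than germinating seeds only in the NIR", {
  sc <- generateScene(sceneSpec(nSeeds = 12, imageSize = 256,
                                nirShift = 0.1, rngSeed = 21))
  lab <- truthLabels(sc$truth)
  bx <- truthBoxes(sc$truth)
  fullMask <- function(i) {
    m <- matrix(FALSE, 256, 256)
    m[(bx$y_min[i] + 1):bx$y_max[i],
      (bx$x_min[i] + 1):bx$x_max[i]][truthMasks(sc$truth)[[i]]] <- TRUE
    m
  }
  spec <- t(vapply(seq_len(nrow(bx)),
                   function(i) meanSpectrum(sc$stack, fullMask(i)),
                   numeric(nBands(sc$stack))))
  agedMean <- colMeans(spec[lab == 0L, ])
  germMean <- colMeans(spec[lab == 1L, ])
  nir <- wavelengths(sc$stack) >= 780
  expect_true(all(agedMean[nir] - germMean[nir] > 0.05))
  expect_true(all(abs(agedMean[!nir] - germMean[!nir]) < 0.01))
})
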