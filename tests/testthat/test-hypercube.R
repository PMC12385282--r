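test_that("reflectance calibration implements the white/dark ratio", {
  w <- c(1000, 1100)
  mk <- function(v) Hypercube(array(v, c(1, 1, 2)), w)
  # raw == white -> 1 everywhere; raw == dark -> 0 everywhere
  white <- mk(100); dark <- mk(20)
  expect_equal(cubeValues(calibrateReflectance(white, white, dark)),
               array(1, c(1, 1, 2)))
  expect_equal(cubeValues(calibrateReflectance(dark, white, dark)),
               array(0, c(1, 1, 2)))
  # single voxel arithmetic: (60 - 20) / (100 - 20) = 0.5
  expect_equal(as.vector(cubeValues(calibrateReflectance(mk(60), white,
                                                         dark))),
               c(0.5, 0.5))
})

test_that("calibration is invariant under a common positive gain", {
  raw <- tinyCube(3, 3, 4, seed = 7)
  white <- Hypercube(cubeValues(raw) + 2, wavelengths(raw))
  dark <- Hypercube(cubeValues(raw) * 0 + 0.1, wavelengths(raw))
  base <- cubeValues(calibrateReflectance(raw, white, dark))
  g <- 3.7
  scaled <- calibrateReflectance(
    Hypercube(g * cubeValues(raw), wavelengths(raw)),
    Hypercube(g * cubeValues(white), wavelengths(raw)),
    Hypercube(g * cubeValues(dark), wavelengths(raw)))
  expect_equal(cubeValues(scaled), base, tolerance = 1e-12)
})

test_that("calibration rejects mismatched or degenerate references", {
  raw <- tinyCube(2, 2, 3)
  small <- tinyCube(2, 2, 2, wavelengths = c(1000, 1100))
  white <- Hypercube(cubeValues(raw) + 1, wavelengths(raw))
  expect_error(calibrateReflectance(raw, small, raw), "dimensions")
  # white == dark at every band -> degenerate, names the offending band
  expect_error(calibrateReflectance(raw, raw, raw), "degenerate reference")
  expect_error(calibrateReflectance(raw, raw, raw), "1000")
  # out-of-range reflectance kept but flagged
  hot <- Hypercube(cubeValues(white) * 5, wavelengths(raw))
  expect_warning(calibrateReflectance(hot, white,
                                      Hypercube(cubeValues(raw) * 0,
                                                wavelengths(raw))),
                 "unclipped")
})

test_that("wavelength crop keeps the inclusive window on the SWIR grid", {
  grid <- defaultWavelengths()
  expect_length(grid, 274)
  cube <- Hypercube(array(1, c(2, 2, length(grid))), grid)
  cropped <- cropWavelengths(cube, 918, 2058)
  # independent count on the arithmetic grid 894 + 5.876 k
  kLo <- ceiling((918 - 894) / 5.876)
  kHi <- floor((2058 - 894) / 5.876)
  expect_equal(dim(cropped)[3], kHi - kLo + 1)   # 194 bands
  expect_equal(dim(cropped)[3], 194L)
  expect_true(all(wavelengths(cropped) >= 918 &
                    wavelengths(cropped) <= 2058))
  # idempotent, full-range identity, empty range
  expect_equal(cubeValues(cropWavelengths(cropped, 918, 2058)),
               cubeValues(cropped))
  full <- cropWavelengths(cube, min(grid), max(grid))
  expect_equal(cubeValues(full), cubeValues(cube))
  expect_error(cropWavelengths(cube, 3000, 4000), "empty range")
  expect_error(cropWavelengths(cube, 2058, 918), "less than")
})

test_that("unfold/refold round trip is exact for any cube and mask", {
  cube <- tinyCube(2, 2, 3)
  dm <- unfold(cube)
  expect_equal(dim(dataMatrix(dm)), c(4L, 3L))
  rt <- refoldCube(dm)
  expect_equal(cubeValues(rt), cubeValues(cube))
  expect_equal(wavelengths(rt), wavelengths(cube))

  # masked round trip for random masks
  for (seed in 1:5) {
    set.seed(seed)
    big <- tinyCube(5, 4, 6, seed = seed)
    mask <- matrix(runif(20) > 0.4, 5, 4)
    if (!any(mask)) mask[1, 1] <- TRUE
    dmM <- unfold(big, RoiMask(mask))
    for (b in seq_len(6)) {
      map <- refold(dataMatrix(dmM)[, b], dmM)
      expect_equal(map[mask], cubeValues(big)[, , b][mask])
      expect_true(all(is.na(map[!mask])))
    }
  }
})

test_that("unfold honours row-major scan order", {
  # 3 x 2 cube, checkerboard mask with 3 selected pixels
  vals <- array(0, c(3, 2, 1))
  vals[, , 1] <- matrix(1:6, 3, 2, byrow = TRUE)   # value = scan position
  cube <- Hypercube(vals, 1000)
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), 3, 2,
                 byrow = TRUE)
  dm <- unfold(cube, RoiMask(mask))
  # hand enumeration: (1,1)=1, then (2,2)=4, then (3,1)=5
  expect_equal(as.vector(dataMatrix(dm)), c(1, 4, 5))
  expect_equal(unname(pixelIndex(dm)),
               matrix(c(1L, 1L, 2L, 2L, 3L, 1L), 3, 2, byrow = TRUE))

  # single-pixel roi returns that pixel's spectrum
  one <- matrix(FALSE, 3, 2); one[2, 1] <- TRUE
  c2 <- tinyCube(3, 2, 4, seed = 3)
  expect_equal(as.vector(dataMatrix(unfold(c2, RoiMask(one)))),
               cubeValues(c2)[2, 1, ])
})

test_that("refold is permutation invariant and shape checked", {
  dm <- unfold(tinyCube(3, 3, 2, seed = 2))
  v <- rnorm(9)
  base <- refold(v, pixelIndex(dm), c(3L, 3L))
  set.seed(1)
  p <- sample(9)
  expect_equal(refold(v[p], pixelIndex(dm)[p, ], c(3L, 3L)), base)
  expect_error(refold(v[1:5], pixelIndex(dm), c(3L, 3L)), "length")
  # single pixel
  m <- refold(4.2, matrix(c(2L, 3L), 1), c(3L, 3L))
  expect_equal(m[2, 3], 4.2)
  expect_equal(sum(is.finite(m)), 1L)
})

test_that("ENVI BIL round trip and byte layout are correct", {
  cube <- tinyCube(4, 4, 5, seed = 9)
  path <- file.path(withr::local_tempdir(), "cube")
  writeCube(cube, path, "envi")
  back <- readCube(path, "envi")
  expect_equal(cubeValues(back), cubeValues(cube), tolerance = 1e-6)
  expect_equal(wavelengths(back), wavelengths(cube), tolerance = 1e-8)

  # BIL definition for a 1 x 2 x 2 cube: line 1 = band1 samples, band2
  # samples
  small <- Hypercube(array(c(1, 2, 3, 4), c(1, 2, 2)), c(1000, 1100))
  # array layout: [1,1,1]=1, [1,2,1]=2, [1,1,2]=3, [1,2,2]=4
  p2 <- file.path(withr::local_tempdir(), "small")
  writeCube(small, p2, "envi")
  bytes <- readBin(p2, "numeric", n = 4, size = 4)
  expect_equal(bytes, c(1, 2, 3, 4))
})

test_that("array+csv dialect round trips exactly and validates", {
  cube <- tinyCube(3, 2, 4, seed = 11)
  stem <- file.path(withr::local_tempdir(), "cube")
  writeCube(cube, stem, "array+csv")
  back <- readCube(stem, "array+csv")
  expect_identical(cubeValues(back), cubeValues(cube))
  expect_equal(wavelengths(back), wavelengths(cube))

  # header/band count mismatch is a format error
  wl <- read.csv(paste0(stem, "_wavelengths.csv"))
  write.csv(wl[1:3, , drop = FALSE], paste0(stem, "_wavelengths.csv"),
            row.names = FALSE)
  expect_error(readCube(stem, "array+csv"), "format error")
})

test_that("Hypercube validity enforces the wavelength contract", {
  expect_error(Hypercube(array(1, c(2, 2, 3)), c(1000, 1100)),
               "band dimension")
  expect_error(Hypercube(array(1, c(2, 2, 3)), c(1200, 1100, 1000)),
               "increasing")
  expect_error(Hypercube(array(c(1, NA), c(1, 1, 2)), c(1000, 1100)),
               "finite")
})
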