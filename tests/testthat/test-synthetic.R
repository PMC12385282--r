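test_that("endmember synthesis places bands where specified", {
  wl <- defaultWavelengths()
  # no peaks -> constant baseline
  flat <- endmemberSpec("flat", data.frame(center = numeric(0),
                                           width = numeric(0),
                                           amplitude = numeric(0),
                                           sign = numeric(0)),
                        baseline = 0.4)
  expect_equal(makeEndmember(flat, wl), rep(0.4, length(wl)))
  # single reflectance peak at 1450 nm -> argmax at the nearest grid band
  one <- endmemberSpec("one", data.frame(center = 1450, width = 30,
                                         amplitude = 0.2, sign = 1),
                       baseline = 0.1)
  s <- makeEndmember(one, wl)
  expect_equal(which.max(s), which.min(abs(wl - 1450)))
  # leaf spec: local extrema at the grid-snapped band centres
  leaf <- defaultEndmembers()$leaf
  sl <- makeEndmember(leaf, wl)
  d <- diff(sl)
  extrema <- which(d[-1] * d[-length(d)] <= 0) + 1L
  for (ctr in leaf$peaks$center) {
    snapped <- which.min(abs(wl - ctr))
    expect_true(min(abs(extrema - snapped)) <= 2,
                label = sprintf("extremum near %g nm", ctr))
  }
  expect_true(all(sl >= 0))
  expect_error(endmemberSpec("bad", data.frame(center = 1450, width = -1,
                                               amplitude = 1, sign = 1)),
               "config error")
  expect_error(makeEndmember(one, seq(1800, 2000, by = 10)),
               "within the wavelength grid")
})

test_that("scenes are bit-reproducible and calibrate back to the truth", {
  a <- makeScene(rows = 10, cols = 8, seed = 5, noiseSd = 0.01)
  b <- makeScene(rows = 10, cols = 8, seed = 5, noiseSd = 0.01)
  expect_identical(cubeValues(a$raw), cubeValues(b$raw))
  expect_identical(a$C, b$C)
  c2 <- makeScene(rows = 10, cols = 8, seed = 6, noiseSd = 0.01)
  expect_false(identical(cubeValues(a$raw), cubeValues(c2$raw)))

  # noiseless: calibration recovers the bilinear truth to float precision
  nf <- makeScene(rows = 6, cols = 6, seed = 2, noiseSd = 0)
  cal <- calibrateReflectance(nf$raw, nf$white, nf$dark)
  expect_equal(cubeValues(cal), cubeValues(nf$noiseFree), tolerance = 1e-10)
  expect_equal(dataMatrix(unfold(cal)), nf$C %*% nf$S, tolerance = 1e-10)
  expect_true(all(nf$C >= 0) && all(nf$S >= 0))
})

test_that("MCR-ALS on a noiseless scene fits to numerical precision", {
  nf <- makeScene(rows = 8, cols = 8, seed = 3, noiseSd = 0)
  dm <- unfold(calibrateReflectance(nf$raw, nf$white, nf$dark))
  fit <- fitMCR(dm, mcrControl(nComponents = 2, tol = 1e-6))
  expect_lt(lofPercent(fit), 1e-6)
})

test_that("empirical scene LOF tracks the injected noise level", {
  # LOF of the noisy cube against its own truth should sit near
  # 100 * noiseSd * mean(signal) / rms(signal)
  rel <- vapply(1:10, function(s) {
    sc <- makeScene(rows = 12, cols = 12, seed = s, noiseSd = 0.02)
    truth <- sc$C %*% sc$S
    noisy <- dataMatrix(unfold(sc$reflectance))
    emp <- lackOfFit(noisy, truth)
    pred <- 100 * 0.02 * mean(truth) / sqrt(mean(truth^2))
    emp / pred
  }, numeric(1))
  expect_true(all(abs(rel - 1) < 0.2))
})

test_that("the concentration series reproduces the study design", {
  ds <- makeConcentrationSeries(seed = 1)
  expect_equal(dim(spectra(ds)), c(120L, 194L))
  y <- concentrations(ds)
  expect_equal(mean(y), 0.030)
  expect_equal(min(y), 0)
  expect_equal(max(y), 0.060)
  expect_equal(sort(unique(y)), c(0, 0.02, 0.04, 0.06))
  expect_equal(length(unique(groupIds(ds))), 60L)
  expect_true(all(table(groupIds(ds)) == 2))
  expect_true(all(wavelengths(ds) >= 918 & wavelengths(ds) <= 2058))
  # reproducibility
  expect_identical(spectra(makeConcentrationSeries(seed = 1)), spectra(ds))
})

test_that("a noiseless series is an exact linear function of concentration", {
  ds <- makeConcentrationSeries(leavesPerLevel = 3, noiseSd = 0,
                                leafEffectSd = 0, seed = 1)
  X <- spectra(ds); y <- concentrations(ds)
  # each band is affine in y: residuals of lm are zero
  for (j in c(1, 50, 100)) {
    fit <- lm(X[, j] ~ y)
    expect_lt(max(abs(residuals(fit))), 1e-12)
  }
})

test_that("reference spectra round trip and interpolate onto new grids", {
  wl <- defaultWavelengths()
  dir <- withr::local_tempdir()
  paths <- makeReferenceSpectra(defaultEndmembers()["chlorfenapyr"], wl,
                                dir)
  back <- readReferenceSpectrum(paths[["chlorfenapyr"]])
  expect_equal(as.numeric(back),
               makeEndmember(defaultEndmembers()$chlorfenapyr, wl))
  expect_false(attr(back, "interpolated"))
  # coarser target grid -> interpolation flagged
  coarse <- seq(1000, 2400, by = 50)
  interp <- readReferenceSpectrum(paths[["chlorfenapyr"]], coarse)
  expect_true(attr(interp, "interpolated"))
  expect_length(as.numeric(interp), length(coarse))

  # reference equal to the generating endmember: near-fixed-point init
  sc <- makeScene(rows = 8, cols = 8, seed = 9, noiseSd = 0)
  dm <- unfold(sc$reflectance)
  fit <- fitMCR(dm, mcrControl(nComponents = 2, init = "reference"),
                referenceSpectra = sc$S)
  expect_true(isConverged(fit))
  expect_lte(nIterations(fit), 5L)
})
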