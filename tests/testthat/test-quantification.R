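test_that("the 70/30 split keeps leaves whole and balances the label mean", {
  ds <- makeConcentrationSeries(seed = 3)
  sp <- splitCalibrationTest(ds, 0.70, seed = 1)
  expect_equal(nrow(spectra(sp$calibration)), 84L)
  expect_equal(nrow(spectra(sp$test)), 36L)
  expect_equal(mean(concentrations(sp$calibration)), 0.030)
  expect_equal(mean(concentrations(sp$test)), 0.030)
  expect_equal(mean(concentrations(ds)), 0.030)
  # no leaf appears on both sides
  expect_length(intersect(groupIds(sp$calibration), groupIds(sp$test)), 0)
  # both ROIs of every leaf travel together
  expect_true(all(table(groupIds(sp$calibration)) == 2))
  # determinism
  sp2 <- splitCalibrationTest(ds, 0.70, seed = 1)
  expect_identical(groupIds(sp2$calibration), groupIds(sp$calibration))
  sp3 <- splitCalibrationTest(ds, 0.70, seed = 2)
  expect_false(identical(groupIds(sp3$calibration),
                         groupIds(sp$calibration)))
  expect_error(splitCalibrationTest(ds, 1.2), "config error")
})

test_that("metrics match hand arithmetic", {
  y <- c(0, 0.02, 0.04, 0.06)
  m <- computeMetrics(y, y + 0.001)
  expect_equal(m$rmse, 0.001)
  expect_equal(m$r2, 0.998, tolerance = 1e-12)
  expect_equal(computeMetrics(y, y), list(r2 = 1, rmse = 0))
  expect_equal(computeMetrics(y, rep(mean(y), 4))$r2, 0)
  expect_error(computeMetrics(rep(1, 3), rep(1, 3)), "zero variance")
  expect_error(computeMetrics(1:3, 1:4), "equal length")
})

test_that("limit of detection follows the 3.3 rho / S rule", {
  expect_equal(limitOfDetection(0, 2), 0)
  expect_equal(limitOfDetection(0.001, 1), 0.0033)
  expect_equal(limitOfDetection(1, 3.3), 1)
  expect_error(limitOfDetection(0.1, 0), "zero slope")
  # linear in rho, inverse in S
  rho <- runif(5); s <- runif(5, 0.5, 2)
  expect_equal(limitOfDetection(3 * rho[1], s[1]),
               3 * limitOfDetection(rho[1], s[1]))
  expect_equal(limitOfDetection(rho[2], 2 * s[2]),
               limitOfDetection(rho[2], s[2]) / 2)
  # from calibration predictions: a perfect fit has LOD 0
  y <- c(0, 0.02, 0.04, 0.06, 0.01, 0.05)
  lod <- lodFromCalibration(y, y)
  expect_equal(lod$lod, 0, tolerance = 1e-12)
  expect_equal(lod$slope, 1, tolerance = 1e-12)
})

test_that("relative improvement reproduces the printed comparisons", {
  # RMSEV 0.0037 -> 0.0012 and R2v 0.97 -> 0.99
  expect_equal(round(relativeImprovement(0.0037, 0.0012, "lower-better"), 2),
               67.57)
  expect_equal(round(relativeImprovement(0.97, 0.99, "higher-better"), 2),
               2.06)
  expect_equal(relativeImprovement(0.5, 0.5, "lower-better"), 0)
  expect_error(relativeImprovement(0, 1), "zero reference")
})

test_that("rank-one linear data are solved exactly by all models", {
  set.seed(2)
  y <- rep(c(0, 0.02, 0.04, 0.06), each = 4)
  X <- outer(y, runif(6, 0.5, 1)) + matrix(0.3, 16, 6)
  ds <- SpectralDataset(X, y, seq(1000, by = 50, length.out = 6),
                        sprintf("g%02d", 1:16))
  pls <- plsrFit(ds, maxComponents = 3, seed = 1)
  expect_equal(pls$ncomp, 1L)
  expect_equal(computeMetrics(y, predict(pls, ds))$r2, 1, tolerance = 1e-9)
  svr <- svrFit(ds, grid = expand.grid(cost = c(10, 1000),
                                       gamma = c(0.01, 0.1),
                                       epsilon = 1e-4), seed = 1)
  expect_gt(computeMetrics(y, predict(svr, ds))$r2, 0.999)
  gpr <- gprFit(ds, kernels = "se", seed = 1)
  expect_gt(computeMetrics(y, predict(gpr, ds))$r2, 0.999999)
})

test_that("double cross-validation is reproducible and leak-free", {
  ds <- makeConcentrationSeries(leavesPerLevel = 6, seed = 4,
                                leafEffectSd = 0)
  d1 <- doubleCrossValidation(ds, plsrFactory(maxComponents = 6), seed = 2)
  d2 <- doubleCrossValidation(ds, plsrFactory(maxComponents = 6), seed = 2)
  expect_identical(d1$r2Val, d2$r2Val)
  expect_identical(d1$rmseVal, d2$rmseVal)
  # noiseless linear data: perfect held-out prediction
  ds0 <- makeConcentrationSeries(leavesPerLevel = 5, seed = 1,
                                 noiseSd = 0, leafEffectSd = 0)
  d0 <- doubleCrossValidation(ds0, plsrFactory(maxComponents = 4), seed = 1)
  expect_equal(d0$r2Val, 1, tolerance = 1e-9)
  expect_lt(d0$rmseVal, 1e-8)
  # metrics are invariant to permuting (reference, prediction) pairs
  yv <- rep(c(0, 0.02, 0.04, 0.06), length.out = 10)
  pv <- yv + rnorm(10, sd = 0.002)
  p <- sample(10)
  expect_equal(computeMetrics(yv, pv), computeMetrics(yv[p], pv[p]))
})

test_that("shuffled labels destroy held-out predictability", {
  ds <- makeConcentrationSeries(leavesPerLevel = 5, seed = 6,
                                leafEffectSd = 0)
  set.seed(9)
  r2s <- vapply(1:20, function(i) {
    # permute labels at the leaf level to respect the grouping
    g <- groupIds(ds)
    ug <- unique(g)
    newLevels <- sample(tapply(concentrations(ds), g, unique)[ug])
    yPerm <- as.numeric(newLevels[match(g, ug)])
    dsP <- SpectralDataset(spectra(ds), yPerm, wavelengths(ds), g)
    doubleCrossValidation(dsP, plsrFactory(maxComponents = 4),
                          seed = i)$r2Val
  }, numeric(1))
  expect_lt(mean(r2s), 0.2)
})

test_that("predicted-vs-true slope is near unity at the stated noise", {
  slopes <- vapply(1:6, function(s) {
    ds <- makeConcentrationSeries(leavesPerLevel = 8, seed = s,
                                  leafEffectSd = 0)
    dcv <- doubleCrossValidation(ds, plsrFactory(maxComponents = 6),
                                 seed = s)
    unname(coef(lm(dcv$predictions$test$predicted ~
                     dcv$predictions$test$reference))[2])
  }, numeric(1))
  expect_true(all(slopes > 0.9 & slopes < 1.1))
})

test_that("held-out residuals show no monotone trend in concentration", {
  rhos <- vapply(1:6, function(s) {
    ds <- makeConcentrationSeries(leavesPerLevel = 8, seed = s + 10,
                                  leafEffectSd = 0)
    dcv <- doubleCrossValidation(ds, plsrFactory(maxComponents = 6),
                                 seed = s)
    resid <- dcv$predictions$test$predicted -
      dcv$predictions$test$reference
    suppressWarnings(cor(resid, dcv$predictions$test$reference,
                         method = "spearman"))
  }, numeric(1))
  expect_lt(median(abs(rhos)), 0.3)
})
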