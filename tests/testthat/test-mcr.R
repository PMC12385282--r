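test_that("lack of fit and explained variance match hand arithmetic", {
  D <- matrix(1, 2, 2)
  # residuals all 0.1: LOF = 100 sqrt(4 * 0.01 / 4) = 10, R2 = 99
  model <- matrix(0.9, 2, 2)
  expect_equal(lackOfFit(D, model), 10)
  expect_equal(explainedVariance(D, model), 99)
  # perfect model and null model
  expect_equal(lackOfFit(D, D), 0)
  expect_equal(explainedVariance(D, D), 100)
  expect_equal(lackOfFit(D, D * 0), 100)
  expect_equal(explainedVariance(D, D * 0), 0)
  expect_error(lackOfFit(D * 0, D), "undefined denominator")
  expect_error(lackOfFit(D, matrix(1, 3, 2)), "shape")
})

test_that("active-set NNLS agrees with the reference solver", {
  skip_if_not_installed("pracma")
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(runif(15 * 4), 15, 4)
    B <- matrix(rnorm(15 * 6), 15, 6)
    ours <- specres:::.nnlsNormal(crossprod(A), crossprod(A, B))$X
    ref <- vapply(seq_len(6),
                  function(j) pracma::lsqnonneg(A, B[, j])$x,
                  numeric(4))
    expect_equal(ours, ref, tolerance = 1e-8)
    expect_true(all(ours >= 0))
  }
})

test_that("noiseless bilinear data are recovered exactly up to permutation and scale", {
  pf <- pureFactorPair(20, 12, seed = 1)
  fit <- fitMCR(pf$D, mcrControl(nComponents = 2, tol = 1e-8))
  expect_lt(lofPercent(fit), 1e-6)
  expect_gt(bestCosines(resolvedSpectra(fit), pf$S), 0.999)
  expect_true(all(abundances(fit) >= 0))
  expect_true(all(resolvedSpectra(fit) >= 0))
  expect_true(isConverged(fit))
  # R2/LOF identity
  expect_equal(r2Percent(fit), 100 * (1 - (lofPercent(fit) / 100)^2),
               tolerance = 1e-9)
})

test_that("initializing at the true spectra is a fixed point", {
  pf <- pureFactorPair(15, 10, seed = 3)
  fit <- fitMCR(pf$D, mcrControl(nComponents = 2, init = "reference"),
                referenceSpectra = pf$S)
  expect_true(isConverged(fit))
  expect_lte(nIterations(fit), 2L)
  expect_lt(lofPercent(fit), 1e-8)
})

test_that("the LOF trace is non-increasing under alternating exact solves", {
  set.seed(5)
  pf <- pureFactorPair(40, 16, seed = 5)
  D <- pf$D + matrix(rnorm(length(pf$D), sd = 0.02 * mean(pf$D)),
                     nrow(pf$D))
  D[D < 0] <- 0
  # deliberately poor initial spectra to force a long trace
  init <- matrix(runif(2 * 16, 0.1, 1), 2, 16)
  fit <- fitMCR(D, mcrControl(nComponents = 2, init = "reference",
                              tol = 1e-4),
                referenceSpectra = init)
  expect_gt(nIterations(fit), 2L)
  expect_true(all(diff(lofTrace(fit)) <= 1e-9))
})

test_that("a third component on a two-component scene stays marginal", {
  pf <- pureFactorPair(40, 16, seed = 8)
  fit <- fitMCR(pf$D, mcrControl(nComponents = 3, tol = 1e-8,
                                 maxIter = 2000))
  props <- suppressWarnings(componentProportions(fit))
  expect_lt(sort(props)[1], 1)
})

test_that("component proportions are percentages that sum to 100", {
  C <- cbind(c(1, 2), c(1, 2))
  expect_equal(componentProportions(C), c(50, 50))
  expect_equal(componentProportions(cbind(c(3, 3), c(1, 1))), c(75, 25))
  expect_equal(componentProportions(matrix(2, 3, 1)), 100)
  expect_equal(sum(componentProportions(matrix(runif(8), 4, 2))), 100,
               tolerance = 1e-9)
  expect_error(componentProportions(matrix(0, 2, 2)), "degenerate")
  expect_error(componentProportions(matrix(-1, 2, 2)), "non-negative")
})

test_that("residue-region selection keeps the top abundances with scan-order ties", {
  map <- matrix(c(10, 1, 2, 9, 3, 8, 4, 7, 5, 6), 2, 5)
  roi <- selectResidueRegions(map, 0.2)
  expect_equal(sum(roi@mask), 2L)
  expect_true(all(map[roi@mask] %in% c(10, 9)))
  # fraction 1 keeps everything
  expect_true(all(selectResidueRegions(map, 1)@mask))
  # constant map: ties resolved by row-major scan order
  flat <- matrix(1, 2, 2)
  roiFlat <- selectResidueRegions(flat, 0.5)
  expect_equal(unname(which(t(roiFlat@mask), arr.ind = FALSE)), c(1L, 2L))
  expect_equal(roiFlat@mask, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_error(selectResidueRegions(map, 0), "config error")
  expect_error(selectResidueRegions(map, 1.2), "config error")
  # NA background is ignored
  withNA <- map; withNA[1, 1] <- NA
  roiNA <- selectResidueRegions(withNA, 0.25)
  expect_equal(sum(roiNA@mask), ceiling(0.25 * 9))
})

test_that("mean-spectrum extraction averages masked pixels per band", {
  cube <- tinyCube(2, 2, 3, seed = 6)
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(as.vector(extractMeanSpectra(cube, RoiMask(m1))),
               cubeValues(cube)[1, 1, ])
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(as.vector(extractMeanSpectra(cube, RoiMask(m2))),
               (cubeValues(cube)[1, 1, ] + cubeValues(cube)[2, 1, ]) / 2)
  # DataMatrix route agrees with the cube route
  dm <- unfold(cube)
  expect_equal(extractMeanSpectra(dm, list(RoiMask(m1), RoiMask(m2))),
               extractMeanSpectra(cube, list(RoiMask(m1), RoiMask(m2))))
})

test_that("component matching assigns factors by correlation", {
  pf <- pureFactorPair(20, 12, seed = 2)
  fit <- fitMCR(pf$D, mcrControl(nComponents = 2, tol = 1e-8))
  idx <- matchComponents(fit, pf$S)
  expect_setequal(idx, 1:2)
  expect_true(all(attr(idx, "correlation") > 0.99))
})
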