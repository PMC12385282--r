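#' Group-aware stratified calibration/test split
#'
#' Allocates whole leaves (groups), not rows, to the calibration and test
#' subsets within each concentration level, so that both regions of
#' interest from one leaf stay on the same side of the split. The number
#' of calibration leaves per level uses largest-remainder rounding with
#' leftover leaves assigned symmetrically from the outermost levels
#' inward, which preserves the label mean exactly for an equally spaced,
#' balanced design (the "balance between the mean and standard deviation"
#' of the subsets).
#'
#' @param ds a [SpectralDataset-class]; each group must sit at a single
#'   concentration level.
#' @param calFraction fraction of leaves allocated to calibration,
#'   in (0, 1); default 0.70.
#' @param seed integer seed for the within-level draw.
#' @return List with elements `calibration` and `test`
#'   ([SpectralDataset-class]s) and `summary` (per-subset mean/SD of the
#'   labels).
#' @examples
#' ds <- makeConcentrationSeries(seed = 1)
#' sp <- splitCalibrationTest(ds, 0.70, seed = 1)
#' nrow(spectra(sp$calibration))  # 84
#' @export
splitCalibrationTest <- function(ds, calFraction = 0.70, seed = 1) {
  stopifnot(is(ds, "SpectralDataset"))
  if (!(calFraction > 0 && calFraction < 1))
    stop("config error: calFraction must be in (0, 1)", call. = FALSE)
  glev <- tapply(ds@y, ds@groups, function(v) {
    u <- unique(v)
    if (length(u) != 1L)
      stop("each group must have a single concentration level",
           call. = FALSE)
    u
  })
  levels <- sort(unique(as.numeric(glev)))
  nL <- length(levels)
  perLevel <- vapply(levels, function(l) sum(glev == l), numeric(1))
  totalCal <- round(calFraction * length(glev))
  base <- floor(calFraction * perLevel)
  extra <- totalCal - sum(base)
  # symmetric outside-in order: 1, L, 2, L-1, ...
  half <- seq_len(ceiling(nL / 2))
  symOrder <- as.vector(rbind(half, nL + 1L - half))
  symOrder <- unique(symOrder[symOrder >= 1 & symOrder <= nL])
  counts <- base
  i <- 1L
  while (extra > 0L && i <= 10L * nL) {
    j <- symOrder[(i - 1L) %% nL + 1L]
    if (counts[j] < perLevel[j]) {
      counts[j] <- counts[j] + 1L
      extra <- extra - 1L
    }
    i <- i + 1L
  }
  calGroups <- withSeed(seed, {
    unlist(lapply(seq_len(nL), function(j) {
      g <- names(glev)[glev == levels[j]]
      sample(g, counts[j])
    }))
  })
  inCal <- ds@groups %in% calGroups
  subsetDs <- function(sel) SpectralDataset(ds@X[sel, , drop = FALSE],
                                            ds@y[sel], ds@wavelengths,
                                            ds@groups[sel])
  cal <- subsetDs(inCal)
  tst <- subsetDs(!inCal)
  summary <- data.frame(
    set = c("full", "calibration", "test"),
    n = c(length(ds@y), sum(inCal), sum(!inCal)),
    mean = c(mean(ds@y), mean(cal@y), mean(tst@y)),
    sd = c(sd(ds@y), sd(cal@y), sd(tst@y)),
    min = c(min(ds@y), min(cal@y), min(tst@y)),
    max = c(max(ds@y), max(cal@y), max(tst@y)))
  list(calibration = cal, test = tst, summary = summary)
}

#' Coefficient of determination and RMSE
#'
#' `R2 = 1 - SS_res / SS_tot` against the mean of `yTrue`; `RMSE` is the
#' root mean squared error, in the units of `y` (percent concentration).
#'
#' @param yTrue,yPred numeric vectors of equal length (at least 2).
#' @return List with `r2` and `rmse`.
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) < 2L)
    stop("yTrue and yPred must have equal length >= 2", call. = FALSE)
  sst <- sum((yTrue - mean(yTrue))^2)
  if (sst == 0) stop("undefined R2: zero variance in yTrue", call. = FALSE)
  list(r2 = 1 - sum((yTrue - yPred)^2) / sst,
       rmse = sqrt(mean((yTrue - yPred)^2)))
}

#' ICH limit of detection
#'
#' \eqn{LOD = 3.3 \rho / S} with \eqn{\rho} the residual standard
#' deviation and \eqn{S} the slope of the calibration
#' predicted-versus-reference regression line.
#'
#' @param residualSd residual standard deviation, percent.
#' @param slope regression slope (nonzero).
#' @return LOD in percent.
#' @export
limitOfDetection <- function(residualSd, slope) {
  if (residualSd < 0) stop("residualSd must be non-negative", call. = FALSE)
  if (slope == 0) stop("degenerate calibration: zero slope", call. = FALSE)
  3.3 * residualSd / slope
}

#' LOD from calibration predictions
#'
#' Regresses predicted on reference concentrations (ordinary least
#' squares), takes the residual standard deviation and slope, and applies
#' [limitOfDetection()].
#'
#' @param yTrue,yPred calibration reference and predicted concentrations.
#' @return List with `lod`, `residualSd`, `slope`.
#' @export
lodFromCalibration <- function(yTrue, yPred) {
  fit <- lm(yPred ~ yTrue)
  # summary.lm warns on essentially perfect fits; sigma = 0 is fine here
  rho <- suppressWarnings(summary(fit)$sigma)
  slope <- unname(coef(fit)[2])
  list(lod = limitOfDetection(rho, slope), residualSd = rho, slope = slope)
}

#' Relative improvement between two metric values, percent
#'
#' For error-type metrics (`"lower-better"`), `100 (ref - new) / ref`; for
#' score-type metrics (`"higher-better"`), `100 (new - ref) / ref`.
#'
#' @param metricRef reference (baseline) value, nonzero.
#' @param metricNew new value.
#' @param direction `"lower-better"` or `"higher-better"`.
#' @return Percent change, positive when `metricNew` improves on the
#'   baseline.
#' @examples
#' relativeImprovement(0.0037, 0.0012, "lower-better")  # 67.57
#' relativeImprovement(0.97, 0.99, "higher-better")     # 2.06
#' @export
relativeImprovement <- function(metricRef, metricNew,
                                direction = c("lower-better",
                                              "higher-better")) {
  direction <- match.arg(direction)
  if (metricRef == 0) stop("undefined: zero reference metric", call. = FALSE)
  if (direction == "lower-better") 100 * (metricRef - metricNew) / metricRef
  else 100 * (metricNew - metricRef) / metricRef
}

# ---- baseline models -------------------------------------------------------

#' Partial least squares regression baseline
#'
#' Mean-centered PLSR (via `mixOmics::pls`, regression mode); the number
#' of latent variables is chosen from `1:maxComponents` (capped at the
#' data rank) by lowest RMSE over group-aware inner folds.
#'
#' @param cal calibration [SpectralDataset-class].
#' @param maxComponents largest latent-variable count considered.
#' @param innerFolds inner CV folds.
#' @param seed fold-assignment seed.
#' @return Object of class `plsrModel` with a predict method.
#' @export
plsrFit <- function(cal, maxComponents = 15, innerFolds = 5, seed = 1) {
  stopifnot(is(cal, "SpectralDataset"))
  X <- cal@X; y <- cal@y
  colnames(X) <- paste0("b", seq_len(ncol(X)))   # mixOmics matches by name
  # cap latent variables at the centered-data rank (degenerate designs,
  # e.g. a noiseless rank-one response, make later components singular)
  rank <- qr(sweep(X, 2L, colMeans(X)))$rank
  ncompGrid <- seq_len(max(1L, min(maxComponents, rank, nrow(X) - 1L)))
  folds <- .groupFolds(cal@groups, innerFolds, seed)
  press <- matrix(NA_real_, max(folds), length(ncompGrid))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    if (!any(tr) || !any(!tr)) next
    Xtr <- X[tr, , drop = FALSE]
    aMax <- min(max(ncompGrid), sum(tr) - 1L,
                qr(sweep(Xtr, 2L, colMeans(Xtr)))$rank)
    fit <- mixOmics::pls(Xtr, y[tr], ncomp = aMax,
                         mode = "regression", scale = FALSE)
    pr <- predict(fit, X[!tr, , drop = FALSE])$predict
    for (a in ncompGrid[ncompGrid <= aMax])
      press[f, a] <- mean((pr[, 1L, a] - y[!tr])^2)
  }
  cvRMSE <- sqrt(colMeans(press, na.rm = TRUE))
  ncomp <- ncompGrid[which.min(cvRMSE)]
  fit <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                       scale = FALSE)
  structure(list(fit = fit, ncomp = ncomp, cvRMSE = cvRMSE,
                 wavelengths = cal@wavelengths),
            class = "plsrModel")
}

#' @export
predict.plsrModel <- function(object, newdata, ...) {
  Xn <- if (is(newdata, "SpectralDataset")) newdata@X else as.matrix(newdata)
  colnames(Xn) <- paste0("b", seq_len(ncol(Xn)))
  pr <- predict(object$fit, Xn)$predict
  as.vector(pr[, 1L, object$ncomp])
}

#' Support vector regression baseline
#'
#' RBF-kernel epsilon-SVR on standardized spectra; cost, gamma and epsilon
#' are chosen over a logarithmic grid by lowest RMSE over group-aware
#' inner folds.
#'
#' @param cal calibration [SpectralDataset-class].
#' @param grid data.frame of candidate (cost, gamma, epsilon) rows;
#'   defaults to cost 1e-2..1e3, gamma 1e-4..1e1, epsilon 1e-4..1e-2.
#' @param innerFolds inner CV folds.
#' @param seed fold-assignment seed.
#' @return Object of class `svrModel` with a predict method.
#' @export
svrFit <- function(cal, grid = NULL, innerFolds = 5, seed = 1) {
  stopifnot(is(cal, "SpectralDataset"))
  if (is.null(grid))
    grid <- expand.grid(cost = 10^seq(-2, 3), gamma = 10^seq(-4, 1),
                        epsilon = c(1e-4, 1e-3, 1e-2))
  X <- cal@X; y <- cal@y
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd); scl[!is.finite(scl) | scl <= 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  folds <- .groupFolds(cal@groups, innerFolds, seed)
  score <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- numeric(0)
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      if (!any(tr) || !any(!tr)) next
      m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
                      type = "eps-regression", kernel = "radial",
                      cost = grid$cost[i], gamma = grid$gamma[i],
                      epsilon = grid$epsilon[i], scale = FALSE)
      errs <- c(errs, (predict(m, Xs[!tr, , drop = FALSE]) - y[!tr])^2)
    }
    sqrt(mean(errs))
  }, numeric(1))
  best <- grid[which.min(score), ]
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = best$cost, gamma = best$gamma,
                    epsilon = best$epsilon, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl, best = best,
                 cvRMSE = min(score), wavelengths = cal@wavelengths),
            class = "svrModel")
}

#' @export
predict.svrModel <- function(object, newdata, ...) {
  Xn <- if (is(newdata, "SpectralDataset")) newdata@X else as.matrix(newdata)
  Xs <- sweep(sweep(Xn, 2L, object$center), 2L, object$scale, "/")
  as.vector(predict(object$fit, Xs))
}

# ---- model factories and nested evaluation ---------------------------------

#' Model factories for nested cross-validation
#'
#' Each factory returns `function(cal, innerFolds, seed)` producing a
#' fitted model with a `predict` method, so [doubleCrossValidation()] can
#' treat GPR, PLSR and SVR uniformly.
#'
#' @param kernels kernel menu for GPR.
#' @param nRestarts MLE restarts for GPR.
#' @param maxComponents PLSR latent-variable ceiling.
#' @param grid SVR hyperparameter grid (NULL for default).
#' @return A model factory function.
#' @name modelFactories
NULL

#' @rdname modelFactories
#' @export
gprFactory <- function(kernels = c("se", "matern32", "matern52", "rq"),
                       nRestarts = 5) {
  function(cal, innerFolds, seed)
    gprFit(cal, kernels = kernels, innerFolds = innerFolds, seed = seed,
           nRestarts = nRestarts)
}

#' @rdname modelFactories
#' @export
plsrFactory <- function(maxComponents = 15) {
  function(cal, innerFolds, seed)
    plsrFit(cal, maxComponents = maxComponents, innerFolds = innerFolds,
            seed = seed)
}

#' @rdname modelFactories
#' @export
svrFactory <- function(grid = NULL) {
  function(cal, innerFolds, seed)
    svrFit(cal, grid = grid, innerFolds = innerFolds, seed = seed)
}

#' Double (nested) cross-validation
#'
#' Outer loop: the group-aware 70/30 split of [splitCalibrationTest()]
#' (optionally repeated with distinct seeds, metrics averaged). Inner
#' loop: whatever fold-based selection the model factory performs on the
#' calibration subset (kernel family for GPR, latent variables for PLSR,
#' cost/gamma/epsilon for SVR). Held-out metrics are computed on outer
#' test predictions only; test rows are never touched during fitting.
#'
#' @param ds a [SpectralDataset-class].
#' @param modelFactory a factory from [gprFactory()], [plsrFactory()] or
#'   [svrFactory()].
#' @param calFraction outer split fraction.
#' @param innerFolds inner CV folds.
#' @param nRepeats number of outer splits to average.
#' @param seed root seed; repeat r uses `seed + r - 1`.
#' @return List: `r2Val`, `rmseVal` (averaged), `r2Cal`, `rmseCal` (first
#'   repeat), `model` (first repeat), `predictions` (first repeat
#'   calibration/test data.frames), `perRepeat`.
#' @export
doubleCrossValidation <- function(ds, modelFactory, calFraction = 0.70,
                                  innerFolds = 5, nRepeats = 1, seed = 1) {
  stopifnot(is(ds, "SpectralDataset"))
  reps <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    sr <- seed + r - 1L
    sp <- splitCalibrationTest(ds, calFraction, seed = sr)
    model <- modelFactory(sp$calibration, innerFolds, sr)
    predCal <- predict(model, sp$calibration)
    predTest <- predict(model, sp$test)
    mc <- computeMetrics(sp$calibration@y, predCal)
    mv <- computeMetrics(sp$test@y, predTest)
    reps[[r]] <- list(model = model, split = sp,
                      r2Cal = mc$r2, rmseCal = mc$rmse,
                      r2Val = mv$r2, rmseVal = mv$rmse,
                      predCal = predCal, predTest = predTest)
  }
  first <- reps[[1L]]
  list(r2Val = mean(vapply(reps, `[[`, numeric(1), "r2Val")),
       rmseVal = mean(vapply(reps, `[[`, numeric(1), "rmseVal")),
       r2Cal = first$r2Cal, rmseCal = first$rmseCal,
       model = first$model,
       predictions = list(
         calibration = data.frame(reference = first$split$calibration@y,
                                  predicted = first$predCal),
         test = data.frame(reference = first$split$test@y,
                           predicted = first$predTest)),
       perRepeat = lapply(reps, function(x)
         c(r2Val = x$r2Val, rmseVal = x$rmseVal)))
}

# Assemble a RegressionReport from a doubleCrossValidation result.
.makeReport <- function(dcv, name, kernel = "") {
  lod <- lodFromCalibration(dcv$predictions$calibration$reference,
                            dcv$predictions$calibration$predicted)
  new("RegressionReport", modelName = name,
      r2Cal = dcv$r2Cal, rmseCal = dcv$rmseCal,
      r2Val = dcv$r2Val, rmseVal = dcv$rmseVal,
      predictions = dcv$predictions, chosenKernel = kernel,
      lodPercent = lod$lod)
}
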