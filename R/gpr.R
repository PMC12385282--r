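# ---- kernels ---------------------------------------------------------------

.kernelFamilies <- c("se", "matern32", "matern52", "rq")

# Covariance from a squared-distance matrix. Isotropic kernels on the
# Euclidean distance between (standardized) spectra:
#   se:        s2 * exp(-r^2 / (2 l^2))
#   matern32:  s2 * (1 + sqrt(3) r / l) exp(-sqrt(3) r / l)
#   matern52:  s2 * (1 + sqrt(5) r / l + 5 r^2 / (3 l^2)) exp(-sqrt(5) r / l)
#   rq:        s2 * (1 + r^2 / (2 a l^2))^(-a)
.kernelEval <- function(d2, family, lengthScale, signalVar, alpha = 1) {
  l2 <- lengthScale^2
  switch(family,
    se = signalVar * exp(-d2 / (2 * l2)),
    matern32 = {
      q <- sqrt(3 * d2) / lengthScale
      signalVar * (1 + q) * exp(-q)
    },
    matern52 = {
      q <- sqrt(5 * d2) / lengthScale
      signalVar * (1 + q + 5 * d2 / (3 * l2)) * exp(-q)
    },
    rq = signalVar * (1 + d2 / (2 * alpha * l2))^(-alpha),
    stop("unknown kernel family: ", family, call. = FALSE))
}

.sqDist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Kernel hyperparameter container
#'
#' @param family one of `"se"`, `"matern32"`, `"matern52"`, `"rq"`.
#' @param lengthScale,signalVar,noiseVar positive hyperparameters.
#' @param alpha rational-quadratic shape (ignored otherwise).
#' @return A list of class `KernelSpec`.
#' @export
kernelSpec <- function(family = "se", lengthScale = 1, signalVar = 1,
                       noiseVar = 0.1, alpha = 1) {
  family <- match.arg(family, .kernelFamilies)
  if (any(c(lengthScale, signalVar, noiseVar, alpha) <= 0))
    stop("all kernel hyperparameters must be positive", call. = FALSE)
  structure(list(family = family, lengthScale = lengthScale,
                 signalVar = signalVar, noiseVar = noiseVar, alpha = alpha),
            class = "KernelSpec")
}

# Negative log marginal likelihood for log-parameterized hyperparameters.
# par = (log l, log s2, log noise [, log alpha]); d2 precomputed.
.gprNLL <- function(par, d2, yc, family, jitter) {
  l <- exp(par[1]); s2 <- exp(par[2]); nv <- exp(par[3])
  a <- if (family == "rq") exp(par[4]) else 1
  n <- length(yc)
  K <- .kernelEval(d2, family, l, s2, a)
  diag(K) <- diag(K) + nv + jitter
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  sum(log(diag(L))) + 0.5 * sum(yc * alpha) + 0.5 * n * log(2 * pi)
}

# Maximum (marginal) likelihood fit of one kernel family with seeded
# multi-restart L-BFGS-B on log-hyperparameters.
.gprMLE <- function(X, y, family, nRestarts = 5, seed = 1) {
  n <- nrow(X)
  d2 <- .sqDist(X)
  ybar <- mean(y)
  yc <- y - ybar
  vy <- max(var(y), 1e-12)
  med <- sqrt(median(d2[upper.tri(d2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  jitter <- 1e-10 * vy
  npar <- if (family == "rq") 4L else 3L
  center <- c(log(med), log(vy), log(0.05 * vy), 0)[seq_len(npar)]
  lower <- center - c(7, 10, 15, 4)[seq_len(npar)]
  upper <- center + c(7, 8, 4, 6)[seq_len(npar)]

  starts <- withSeed(seed, {
    s <- matrix(rnorm(npar * max(nRestarts - 1, 0), sd = 1.5),
                ncol = npar)
    rbind(center, sweep(s, 2L, center, "+"))
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[i, ], lower), upper)
    fit <- tryCatch(
      optim(p0, .gprNLL, d2 = d2, yc = yc, family = family,
            jitter = jitter, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("GPR likelihood optimization failed", call. = FALSE)
  p <- best$par
  spec <- kernelSpec(family, exp(p[1]), exp(p[2]), exp(p[3]),
                     if (family == "rq") exp(p[4]) else 1)
  K <- .kernelEval(d2, family, spec$lengthScale, spec$signalVar, spec$alpha)
  diag(K) <- diag(K) + spec$noiseVar + jitter
  L <- chol(K)
  list(spec = spec, X = X, ybar = ybar, L = L,
       alpha = backsolve(L, forwardsolve(t(L), yc)),
       nll = best$value, jitter = jitter)
}

#' Gaussian process regression with kernel selection
#'
#' Fits a zero-mean GP to centered concentrations on standardized spectra.
#' For every kernel family in the menu, hyperparameters (length scale,
#' signal variance, noise variance, RQ shape) are set by maximizing the
#' Gaussian marginal log-likelihood with seeded multi-restart L-BFGS-B; the
#' family is then chosen by the lowest mean RMSE over `innerFolds`
#' group-aware cross-validation folds of the calibration set, with ties
#' going to the simpler family (in menu order). The chosen family is
#' refitted on the full calibration set.
#'
#' @param cal calibration [SpectralDataset-class].
#' @param kernels kernel family menu, simplest first.
#' @param innerFolds number of inner CV folds (default 5).
#' @param seed integer seed controlling fold assignment and restarts.
#' @param nRestarts MLE restarts per family and fold.
#' @param standardize center/scale each band using calibration statistics
#'   before computing distances.
#' @return An object of class `gprModel` with a [predict.gprModel()]
#'   method; element `chosenKernel` names the selected family and
#'   `innerRMSE` holds the per-family CV scores.
#' @export
gprFit <- function(cal, kernels = c("se", "matern32", "matern52", "rq"),
                   innerFolds = 5, seed = 1, nRestarts = 5,
                   standardize = TRUE) {
  stopifnot(is(cal, "SpectralDataset"))
  kernels <- match.arg(kernels, .kernelFamilies, several.ok = TRUE)
  X <- cal@X; y <- cal@y
  ctr <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardize) {
    s <- apply(X, 2L, sd)
    s[!is.finite(s) | s <= 0] <- 1
    s
  } else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  folds <- .groupFolds(cal@groups, innerFolds, seed)
  innerRMSE <- rep(NA_real_, length(kernels))
  names(innerRMSE) <- kernels
  if (length(kernels) > 1L && max(folds) >= 2L) {
    for (fam in kernels) {
      errs <- numeric(0)
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        if (!any(tr) || !any(!tr)) next
        m <- .gprMLE(Xs[tr, , drop = FALSE], y[tr], fam, nRestarts,
                     seed + f)
        pv <- .gprPredictCore(m, Xs[!tr, , drop = FALSE])$mean
        errs <- c(errs, (pv - y[!tr])^2)
      }
      innerRMSE[fam] <- sqrt(mean(errs))
    }
    chosen <- kernels[which.min(innerRMSE)]  # ties -> earliest (simplest)
  } else {
    chosen <- kernels[1L]
  }
  m <- .gprMLE(Xs, y, chosen, nRestarts, seed)
  structure(list(core = m, center = ctr, scale = scl,
                 chosenKernel = chosen, innerRMSE = innerRMSE,
                 wavelengths = cal@wavelengths, standardize = standardize),
            class = "gprModel")
}

.gprPredictCore <- function(m, Xnew) {
  ks <- .kernelEval(.sqDist(Xnew, m$X), m$spec$family, m$spec$lengthScale,
                    m$spec$signalVar, m$spec$alpha)
  mu <- as.vector(ks %*% m$alpha) + m$ybar
  v <- forwardsolve(t(m$L), t(ks))
  pv <- m$spec$signalVar + m$spec$noiseVar - colSums(v^2)
  pv[pv < 0] <- 0
  list(mean = mu, var = pv)
}

#' Predict from a fitted GP model
#'
#' Posterior predictive mean \eqn{k_*^T (K + \sigma^2 I)^{-1} y} (plus the
#' fitted constant) and, optionally, the predictive variance.
#'
#' @param object a `gprModel` from [gprFit()].
#' @param newdata matrix of spectra or a [SpectralDataset-class] on the
#'   training wavelength grid.
#' @param se.fit also return predictive variances.
#' @param ... unused.
#' @return Numeric vector of means, or a list `mean`/`var`.
#' @export
predict.gprModel <- function(object, newdata, se.fit = FALSE, ...) {
  Xn <- if (is(newdata, "SpectralDataset")) newdata@X else as.matrix(newdata)
  if (ncol(Xn) != length(object$center))
    stop("shape error: newdata is not on the training wavelength grid",
         call. = FALSE)
  Xs <- sweep(sweep(Xn, 2L, object$center), 2L, object$scale, "/")
  out <- .gprPredictCore(object$core, Xs)
  if (se.fit) out else out$mean
}

# Group-aware fold assignment: whole groups are shuffled (seeded) and
# dealt round-robin, so folds never split a leaf.
.groupFolds <- function(groups, nFolds, seed = 1) {
  ug <- unique(groups)
  nFolds <- min(nFolds, length(ug))
  perm <- withSeed(seed, sample(length(ug)))
  gf <- integer(length(ug))
  gf[perm] <- rep(seq_len(nFolds), length.out = length(ug))
  gf[match(groups, ug)]
}
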