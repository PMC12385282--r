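# Non-negative (or plain) least squares on the normal equations,
# shared by the ALS sweeps and SIMPLISMA spectra resolution.
.nnlsSolve <- function(AtA, AtB, nonneg = TRUE) {
  if (nonneg) {
    .nnlsNormal(AtA, AtB)
  } else {
    X <- tryCatch(solve(AtA, AtB), error = function(e) {
      ridge <- 1e-10 * (sum(diag(AtA)) / nrow(AtA) + 1)
      solve(AtA + diag(ridge, nrow(AtA)), AtB)
    })
    list(X = X, nRidge = 0L)
  }
}

#' Lack of fit of a bilinear model, percent
#'
#' \eqn{LOF = 100 \sqrt{\sum e_{ij}^2 / \sum d_{ij}^2}} with residuals
#' \eqn{e = D - \hat D}.
#'
#' @param D data matrix (or [DataMatrix-class]).
#' @param model fitted reconstruction \eqn{C S}, same shape as `D`.
#' @return Percent lack of fit.
#' @export
lackOfFit <- function(D, model) {
  if (is(D, "DataMatrix")) D <- D@D
  if (!identical(dim(D), dim(model)))
    stop("D and model must have identical shapes", call. = FALSE)
  ssd <- sum(D^2)
  if (ssd == 0) stop("undefined denominator: D is all zero", call. = FALSE)
  100 * sqrt(sum((D - model)^2) / ssd)
}

#' Explained variance of a bilinear model, percent
#'
#' \eqn{R^2 = 100 (\sum d^2 - \sum e^2) / \sum d^2}; identically
#' \eqn{100 (1 - (LOF/100)^2)}.
#'
#' @inheritParams lackOfFit
#' @return Percent explained variance.
#' @export
explainedVariance <- function(D, model) {
  if (is(D, "DataMatrix")) D <- D@D
  if (!identical(dim(D), dim(model)))
    stop("D and model must have identical shapes", call. = FALSE)
  ssd <- sum(D^2)
  if (ssd == 0) stop("undefined denominator: D is all zero", call. = FALSE)
  100 * (ssd - sum((D - model)^2)) / ssd
}

#' Control parameters for MCR-ALS
#'
#' @param nComponents number of components `k` (the two-component model is
#'   the default for a leaf-plus-residue scene).
#' @param init `"simplisma"` (pure-variable selection) or `"reference"`
#'   (supplied pure reference spectra).
#' @param nonnegC,nonnegS apply non-negativity to abundances / spectra.
#' @param tol convergence tolerance: relative change of LOF between
#'   consecutive sweeps, in percent (default 0.1).
#' @param maxIter sweep cap (default 10000).
#' @param normalize rescale each resolved spectrum to unit maximum after
#'   every sweep (the inverse scale is absorbed into the abundances).
#' @param offsetPercent SIMPLISMA noise offset.
#' @return A validated list of class `MCRControl`.
#' @export
mcrControl <- function(nComponents = 2L, init = c("simplisma", "reference"),
                       nonnegC = TRUE, nonnegS = TRUE, tol = 0.1,
                       maxIter = 10000L, normalize = TRUE,
                       offsetPercent = 3) {
  init <- match.arg(init)
  if (nComponents < 1) stop("nComponents must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (maxIter < 1) stop("maxIter must be >= 1", call. = FALSE)
  structure(list(nComponents = as.integer(nComponents), init = init,
                 nonnegC = nonnegC, nonnegS = nonnegS, tol = tol,
                 maxIter = as.integer(maxIter), normalize = normalize,
                 offsetPercent = offsetPercent),
            class = "MCRControl")
}

#' Constrained MCR-ALS bilinear unmixing
#'
#' Alternating least squares for the bilinear model \eqn{D = C S + E}
#' (`S` rows are component spectra). Each sweep solves the two
#' conditionally optimal subproblems exactly: row-wise active-set
#' non-negative least squares for `C` given `S`, then for `S` given `C`.
#' Because each half-update is optimal, the lack-of-fit trace is
#' non-increasing; iteration stops when the relative LOF change drops
#' below `tol` percent or `maxIter` sweeps are reached.
#'
#' @param D a [DataMatrix-class] or a pixels-by-bands matrix.
#' @param control an [mcrControl()] list.
#' @param referenceSpectra optional `k x n_bands` matrix of initial spectra
#'   on `D`'s wavelength grid (required when `control$init ==
#'   "reference"`).
#' @return An [MCRResult-class].
#' @examples
#' S <- rbind(c(1, 0.2, 0), c(0, 0.3, 1))
#' C <- matrix(runif(40), 20, 2)
#' fit <- fitMCR(C %*% S, mcrControl(nComponents = 2),
#'               referenceSpectra = NULL)
#' lofPercent(fit)
#' @export
fitMCR <- function(D, control = mcrControl(), referenceSpectra = NULL) {
  wl <- if (is(D, "DataMatrix")) D@wavelengths else
    as.numeric(seq_len(ncol(D)))
  Dm <- if (is(D, "DataMatrix")) D@D else as.matrix(D)
  if (!all(is.finite(Dm))) stop("data error: D must be finite", call. = FALSE)
  k <- control$nComponents

  if (control$init == "reference") {
    if (is.null(referenceSpectra))
      stop("reference init requires 'referenceSpectra'", call. = FALSE)
    S <- as.matrix(referenceSpectra)
    if (ncol(S) != ncol(Dm))
      stop("referenceSpectra must be on D's wavelength grid", call. = FALSE)
    if (nrow(S) != k)
      stop("referenceSpectra must have nComponents rows", call. = FALSE)
  } else {
    S <- simplismaInit(Dm, k, control$offsetPercent)
    attributes(S)[c("pureVariables", "purity")] <- NULL
  }
  if (control$nonnegS) S[S < 0] <- 0
  if (control$normalize) {
    mx <- apply(S, 1L, max)
    mx[mx <= 0] <- 1
    S <- S / mx
  }

  nRidge <- 0L
  lofPrev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  C <- NULL
  for (it in seq_len(control$maxIter)) {
    cs <- .nnlsSolve(tcrossprod(S), S %*% t(Dm), control$nonnegC)
    C <- t(cs$X)
    ss <- .nnlsSolve(crossprod(C), crossprod(C, Dm), control$nonnegS)
    S <- ss$X
    nRidge <- nRidge + cs$nRidge + ss$nRidge
    if (control$normalize) {
      mx <- apply(S, 1L, max)
      pos <- mx > 0
      S[pos, ] <- S[pos, , drop = FALSE] / mx[pos]
      C[, pos] <- sweep(C[, pos, drop = FALSE], 2L, mx[pos], "*")
    }
    lof <- lackOfFit(Dm, C %*% S)
    trace <- c(trace, lof)
    if (lof < 1e-10) { converged <- TRUE; break }
    if (is.finite(lofPrev) && lofPrev > 0 &&
        abs(lofPrev - lof) / lofPrev * 100 < control$tol) {
      converged <- TRUE
      break
    }
    lofPrev <- lof
  }
  if (nRidge > 0)
    warning(sprintf("rank-deficient ALS subproblem: ridge fallback used %d time(s)",
                    nRidge), call. = FALSE)
  lof <- trace[length(trace)]
  .MCRResult(C = C, S = S, lofPercent = lof,
             r2Percent = 100 * (1 - (lof / 100)^2), nIter = length(trace),
             converged = converged, lofTrace = trace, wavelengths = wl,
             meta = list(init = control$init, nonnegC = control$nonnegC,
                         nonnegS = control$nonnegS, tol = control$tol,
                         nRidge = nRidge))
}

#' Component proportions, percent
#'
#' Share of total abundance carried by each component:
#' `100 * colSums(C) / sum(C)`.
#'
#' @param C abundance matrix (pixels x components) or an
#'   [MCRResult-class].
#' @return Numeric vector summing to 100.
#' @export
componentProportions <- function(C) {
  if (is(C, "MCRResult")) C <- C@C
  if (any(C < 0)) stop("C must be non-negative", call. = FALSE)
  tot <- sum(C)
  if (tot == 0) stop("degenerate: C is all zero", call. = FALSE)
  100 * colSums(C) / tot
}

#' Select the highest-abundance residue regions
#'
#' Mask of the `ceiling(topFraction * n)` finite pixels with the largest
#' abundance; ties are broken by row-major scan order.
#'
#' @param map abundance map (matrix, possibly with NA background).
#' @param topFraction fraction of finite pixels to keep, in (0, 1].
#' @param label mask label.
#' @return A [RoiMask-class].
#' @export
selectResidueRegions <- function(map, topFraction = 0.2, label = "residue") {
  if (!(topFraction > 0 && topFraction <= 1))
    stop("config error: topFraction must be in (0, 1]", call. = FALSE)
  fin <- which(is.finite(map))
  if (!length(fin)) stop("map has no finite pixels", call. = FALSE)
  m <- ceiling(topFraction * length(fin))
  # row-major scan position for deterministic tie-breaking
  rows <- (fin - 1L) %% nrow(map) + 1L
  cols <- (fin - 1L) %/% nrow(map) + 1L
  scanPos <- (rows - 1L) * ncol(map) + cols
  ord <- order(-map[fin], scanPos)
  keep <- fin[ord[seq_len(m)]]
  mask <- matrix(FALSE, nrow(map), ncol(map))
  mask[keep] <- TRUE
  RoiMask(mask, label)
}

#' Mean spectrum per region of interest
#'
#' Per-band arithmetic mean over the pixels of each mask.
#'
#' @param x a [Hypercube-class] or [DataMatrix-class].
#' @param masks a [RoiMask-class] or list of them.
#' @return Matrix with one mean spectrum per mask (rows named by mask
#'   label) and the wavelength axis as an attribute.
#' @export
extractMeanSpectra <- function(x, masks) {
  if (is(masks, "RoiMask")) masks <- list(masks)
  if (!length(masks)) stop("empty selection: no masks given", call. = FALSE)
  if (is(x, "DataMatrix")) {
    dims <- x@spatialDims
    lin <- (x@pixelIndex[, 2L] - 1L) * dims[1L] + x@pixelIndex[, 1L]
    rows <- lapply(masks, function(mk) {
      sel <- lin %in% which(mk@mask)
      if (!any(sel)) stop("empty selection: mask covers no pixels of D",
                          call. = FALSE)
      colMeans(x@D[sel, , drop = FALSE])
    })
    wl <- x@wavelengths
  } else {
    rows <- lapply(masks, function(mk) colMeans(unfold(x, mk)@D))
    wl <- x@wavelengths
  }
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(masks, function(mk) mk@label, character(1))
  attr(out, "wavelengths") <- wl
  out
}

#' Match resolved components to reference spectra
#'
#' Greedy assignment of resolved spectra to references by maximal Pearson
#' correlation; used to decide which resolved factor is the residue.
#'
#' @param S resolved spectra (components x bands) or an [MCRResult-class].
#' @param reference reference spectra matrix (rows on the same grid).
#' @return Integer vector: for each reference row, the index of the
#'   matching resolved component; correlations as attribute `correlation`.
#' @export
matchComponents <- function(S, reference) {
  if (is(S, "MCRResult")) S <- S@S
  reference <- as.matrix(reference)
  cc <- matrix(NA_real_, nrow(reference), nrow(S))
  for (i in seq_len(nrow(reference)))
    for (j in seq_len(nrow(S)))
      cc[i, j] <- suppressWarnings(cor(reference[i, ], S[j, ]))
  cc[!is.finite(cc)] <- -Inf
  assigned <- integer(nrow(reference))
  avail <- seq_len(nrow(S))
  for (i in order(apply(cc, 1L, max), decreasing = TRUE)) {
    j <- avail[which.max(cc[i, avail])]
    assigned[i] <- j
    avail <- setdiff(avail, j)
    if (!length(avail)) break
  }
  structure(assigned,
            correlation = cc[cbind(seq_len(nrow(reference)), assigned)])
}

#' Export resolved spectra as CSV
#'
#' @param res an [MCRResult-class].
#' @param path output CSV (columns: wavelength, one per component).
#' @param names optional component names.
#' @export
writeResolvedSpectra <- function(res, path, names = NULL) {
  stopifnot(is(res, "MCRResult"))
  k <- nrow(res@S)
  if (is.null(names)) names <- paste0("component", seq_len(k))
  df <- data.frame(wavelength = res@wavelengths, t(res@S))
  colnames(df) <- c("wavelength", names)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
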