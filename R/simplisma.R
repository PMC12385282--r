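#' SIMPLISMA pure-variable initialization
#'
#' Simple-to-use self-modeling mixture analysis: selects `k` "pure"
#' spectral variables (bands) whose intensity is dominated by a single
#' mixture component, then resolves initial spectra from the pure-variable
#' intensity profiles. Purity of band j is \eqn{p_j = \sigma_j / (\mu_j +
#' \delta)} with the noise offset \eqn{\delta} equal to `offsetPercent`/100
#' of the largest band mean; bands after the first are weighted by the
#' determinant of the correlation-around-origin submatrix of the candidates
#' plus already-selected bands, which suppresses bands correlated with
#' earlier picks.
#'
#' The returned initial spectra are the non-negative least-squares
#' resolution of the data on the pure-variable intensity profiles,
#' normalized to unit maximum per component. In the exact bilinear case
#' with truly pure bands this recovers the generating spectra up to scale.
#'
#' @param D a [DataMatrix-class] or a plain pixels-by-bands matrix.
#' @param k number of components to seed.
#' @param offsetPercent noise offset, percent of the maximum band mean
#'   (default 3; the usual working range is 1-5).
#' @return A `k x n_bands` matrix of initial spectra with attributes
#'   `pureVariables` (selected band indices, in selection order) and
#'   `purity` (first-pass purity of every band).
#' @references Windig & Guilment, Anal. Chem. 63 (1991) 1425-1432.
#' @export
simplismaInit <- function(D, k, offsetPercent = 3) {
  if (is(D, "DataMatrix")) D <- D@D
  D <- as.matrix(D)
  n <- nrow(D); nb <- ncol(D)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > nb) stop("config error: k exceeds the number of bands",
                   call. = FALSE)
  if (!all(is.finite(D))) stop("D must be finite", call. = FALSE)
  mu <- colMeans(D)
  sg <- sqrt(colMeans(D^2) - mu^2)        # population SD per band
  sg[sg < 0] <- 0
  if (all(sg < .Machine$double.eps * max(abs(mu), 1)))
    stop("degenerate data: all bands are constant", call. = FALSE)
  delta <- offsetPercent / 100 * max(mu)
  purity1 <- sg / (mu + delta)

  # correlation-around-origin of offset-scaled data
  lambda <- sqrt(mu^2 + (sg + delta)^2)
  Z <- sweep(D, 2L, sqrt(n) * lambda, "/")
  COO <- crossprod(Z)

  sel <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1L) {
      score <- purity1                 # first pick: raw purity
    } else {
      weights <- vapply(seq_len(nb), function(j) {
        if (j %in% sel) return(-Inf)
        det(COO[c(j, sel), c(j, sel), drop = FALSE])
      }, numeric(1))
      score <- weights * purity1
    }
    sel <- c(sel, which.max(score))
  }

  # resolve initial spectra from the pure-variable intensity profiles
  C0 <- D[, sel, drop = FALSE]
  S0 <- .nnlsSolve(crossprod(C0), crossprod(C0, D))$X
  mx <- apply(S0, 1L, max)
  mx[mx <= 0] <- 1
  S0 <- S0 / mx
  structure(S0, pureVariables = sel, purity = purity1)
}
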