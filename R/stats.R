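#' Mann-Whitney U test between two abundance samples
#'
#' Rank-sum comparison with midrank tie handling (delegates to
#' [stats::wilcox.test()]). The exact null distribution is used when the
#' smaller sample has at most 8 observations and the pooled data are
#' tie-free; otherwise the normal approximation with tie-corrected
#' variance and continuity correction applies. The returned `U` counts
#' pairs where `x` exceeds `y` (ties count one half), so
#' `U + UOther = nx * ny` always.
#'
#' @param x,y non-empty numeric vectors (e.g. per-pixel abundances of two
#'   concentration levels).
#' @param alternative test sidedness (default two-sided).
#' @param exact force or forbid the exact null; `NULL` applies the rule
#'   above.
#' @return List: `U`, `UOther`, `p`, `exact` (whether the exact null was
#'   used), `nx`, `ny`.
#' @export
mannWhitneyU <- function(x, y, alternative = "two.sided", exact = NULL) {
  if (!length(x) || !length(y))
    stop("data error: both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- min(nx, ny) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, UOther = nx * ny - U, p = wt$p.value, exact = exact,
       nx = nx, ny = ny)
}

#' U tests between consecutive concentration levels
#'
#' One two-sided Mann-Whitney U test per adjacent pair of levels in
#' concentration order. No multiplicity correction is applied (each pair
#' is reported at the nominal level); pixels are treated as exchangeable
#' observations, so spatial autocorrelation is not accounted for.
#'
#' @param samples named list of numeric vectors, one per level; names are
#'   the level labels.
#' @param levels order of levels; defaults to the numeric sort of the
#'   names (or the given order when names are not numeric).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per adjacent pair: `levelLow`,
#'   `levelHigh`, `U`, `p`, `significant`.
#' @export
consecutiveLevelTests <- function(samples, levels = NULL, alpha = 0.05) {
  if (length(samples) < 2L)
    stop("at least two levels are required", call. = FALSE)
  if (is.null(levels)) {
    nm <- names(samples)
    num <- suppressWarnings(as.numeric(nm))
    levels <- if (!any(is.na(num))) nm[order(num)] else nm
  }
  out <- lapply(seq_len(length(levels) - 1L), function(i) {
    lo <- levels[i]; hi <- levels[i + 1L]
    tt <- mannWhitneyU(samples[[lo]], samples[[hi]])
    data.frame(levelLow = lo, levelHigh = hi, U = tt$U, p = tt$p,
               significant = tt$p < alpha)
  })
  do.call(rbind, out)
}

#' Write a test-result table as CSV
#'
#' @param table data.frame from [consecutiveLevelTests()].
#' @param path output file.
#' @export
writeTestTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
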