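#' Endmember specification
#'
#' A pure-component SWIR spectrum described as a baseline plus signed
#' Gaussian bands: reflectance peaks add, absorption dips subtract, and
#' the result is floored at zero so generated scenes stay in the regime
#' where non-negativity constraints are correct.
#'
#' @param name component name.
#' @param peaks data.frame with columns `center` (nm), `width` (nm,
#'   Gaussian SD), `amplitude` (reflectance units) and `sign` (`1` for a
#'   reflectance peak, `-1` for an absorption dip).
#' @param baseline constant reflectance level.
#' @return List of class `EndmemberSpec`.
#' @export
endmemberSpec <- function(name, peaks, baseline = 0.3) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "width", "amplitude", "sign") %in% names(peaks)))
  if (any(peaks$width <= 0))
    stop("config error: peak widths must be positive", call. = FALSE)
  structure(list(name = name, peaks = peaks, baseline = baseline),
            class = "EndmemberSpec")
}

#' Built-in endmember library
#'
#' Leaf-like and residue-like endmembers whose band positions follow the
#' characteristic SWIR features of perilla leaf (1123, 1170, 1300, 1450,
#' 1652 nm), a chlorfenapyr-like residue (1141, 1217, 1394, 1558, 1860,
#' 1940 nm) and an azoxystrobin-like residue (1217, 1394, 1623, 2030 nm).
#' The water bands (1450, 1940 nm) are absorption dips; widths are in the
#' 15-40 nm range so neighbouring bands stay resolvable on the 5.876 nm
#' grid.
#'
#' @return Named list of [endmemberSpec()] objects: `leaf`,
#'   `chlorfenapyr`, `azoxystrobin`.
#' @export
defaultEndmembers <- function() {
  list(
    leaf = endmemberSpec("leaf", data.frame(
      center = c(1123, 1170, 1300, 1450, 1652),
      width = c(16, 16, 30, 35, 26),
      amplitude = c(0.10, 0.08, 0.14, 0.18, 0.07),
      sign = c(1, 1, 1, -1, -1)), baseline = 0.28),
    chlorfenapyr = endmemberSpec("chlorfenapyr", data.frame(
      center = c(1141, 1217, 1394, 1558, 1860, 1940),
      width = c(18, 20, 24, 26, 24, 32),
      amplitude = c(0.09, 0.12, 0.10, 0.08, 0.09, 0.20),
      sign = c(1, 1, -1, 1, 1, -1)), baseline = 0.38),
    azoxystrobin = endmemberSpec("azoxystrobin", data.frame(
      center = c(1217, 1394, 1623, 2030),
      width = c(20, 24, 26, 30),
      amplitude = c(0.12, 0.08, 0.10, 0.15),
      sign = c(1, -1, 1, 1)), baseline = 0.42))
}

#' Evaluate an endmember spectrum on a wavelength grid
#'
#' @param spec an [endmemberSpec()].
#' @param wavelengths grid in nm; all peak centres must lie inside it.
#' @return Non-negative numeric spectrum, one value per band.
#' @export
makeEndmember <- function(spec, wavelengths = defaultWavelengths()) {
  stopifnot(inherits(spec, "EndmemberSpec"))
  if (any(spec$peaks$center < min(wavelengths) |
          spec$peaks$center > max(wavelengths)))
    stop("peak centres must lie within the wavelength grid", call. = FALSE)
  s <- rep(spec$baseline, length(wavelengths))
  for (i in seq_len(nrow(spec$peaks))) {
    p <- spec$peaks[i, ]
    s <- s + p$sign * p$amplitude *
      exp(-(wavelengths - p$center)^2 / (2 * p$width^2))
  }
  pmax(s, 0)
}

# Smooth non-negative random field in [lo, hi], via separable Gaussian
# smoothing of white noise.
.smoothField <- function(rows, cols, smoothSd = 6, lo = 0, hi = 1) {
  z <- matrix(rnorm(rows * cols), rows, cols)
  kr <- exp(-outer(seq_len(rows), seq_len(rows), "-")^2 / (2 * smoothSd^2))
  kc <- exp(-outer(seq_len(cols), seq_len(cols), "-")^2 / (2 * smoothSd^2))
  kr <- kr / rowSums(kr)
  kc <- kc / rowSums(kc)
  f <- kr %*% z %*% t(kc)
  rng <- range(f)
  if (diff(rng) == 0) return(matrix((lo + hi) / 2, rows, cols))
  lo + (hi - lo) * (f - rng[1]) / diff(rng)
}

#' Generate a synthetic two-endmember scene
#'
#' Builds a bilinear ground truth `D = C S`, refolds it into a
#' reflectance cube, adds Gaussian noise with SD equal to `noiseSd` times
#' the mean signal, and wraps it into a raw/white/dark cube triplet such
#' that [calibrateReflectance()] recovers the noisy reflectance exactly:
#' `raw = R * (white - dark) + dark` with a smooth white-reference field
#' and a low constant dark level. Abundances are spatially heterogeneous
#' and non-negative.
#'
#' @param rows,cols spatial dimensions (default 64 x 64).
#' @param wavelengths band grid (default the 274-band SWIR grid).
#' @param endmembers list of two or more [endmemberSpec()]s (default leaf
#'   + chlorfenapyr-like residue).
#' @param pattern abundance pattern: `"smooth"` random fields, `"blobs"`
#'   (residue droplets on a leaf background), or `"halves"`.
#' @param noiseSd additive noise SD as a fraction of the mean signal
#'   (default 0.01, i.e. 1%).
#' @param concentrationScale multiplier on the residue abundance field.
#' @param seed integer seed; scenes are bit-reproducible per seed.
#' @return List: `raw`, `white`, `dark`, `reflectance` (noisy truth) as
#'   [Hypercube-class]s; `C` (pixels x k, row-major order), `S`
#'   (k x bands); `noiseFree` cube.
#' @export
makeScene <- function(rows = 64, cols = 64,
                      wavelengths = defaultWavelengths(),
                      endmembers = defaultEndmembers()[c("leaf",
                                                         "chlorfenapyr")],
                      pattern = c("smooth", "blobs", "halves"),
                      noiseSd = 0.01, concentrationScale = 1, seed = 1) {
  pattern <- match.arg(pattern)
  if (noiseSd < 0) stop("noiseSd must be non-negative", call. = FALSE)
  k <- length(endmembers)
  S <- t(vapply(endmembers, makeEndmember, numeric(length(wavelengths)),
                wavelengths = wavelengths))
  withSeed(seed, {
    A <- switch(pattern,
      smooth = {
        a <- lapply(seq_len(k), function(i)
          .smoothField(rows, cols, smoothSd = 5 + i, lo = 0.05, hi = 1))
        a[[1]] <- 0.6 + 0.4 * a[[1]]       # dominant leaf background
        a
      },
      blobs = {
        leaf <- .smoothField(rows, cols, 8, 0.7, 1)
        res <- matrix(0, rows, cols)
        nb <- max(3L, round(rows * cols / 300))
        cx <- runif(nb, 1, rows); cy <- runif(nb, 1, cols)
        rad <- runif(nb, 1, max(2.5, rows / 6))
        for (b in seq_len(nb)) {
          d2 <- outer(seq_len(rows), seq_len(cols), function(i, j)
            (i - cx[b])^2 + (j - cy[b])^2)
          res <- res + exp(-d2 / (2 * rad[b]^2))
        }
        res <- res / max(res)
        c(list(leaf, res), lapply(seq_len(max(0, k - 2)), function(i)
          .smoothField(rows, cols, 6, 0, 0.3)))
      },
      halves = {
        left <- matrix(0, rows, cols); left[, seq_len(ceiling(cols / 2))] <- 1
        c(list(0.5 + 0.5 * left, 1 - left),
          lapply(seq_len(max(0, k - 2)), function(i)
            .smoothField(rows, cols, 6, 0, 0.3)))
      })
    if (k >= 2) A[[2]] <- concentrationScale * A[[2]]
    C <- vapply(A, as.vector, numeric(rows * cols))  # column-major for now
    # reorder into row-major scan order to match unfold()
    scan <- order(rep(seq_len(rows), times = cols),
                  rep(seq_len(cols), each = rows))
    C <- C[scan, , drop = FALSE]

    truth <- C %*% S
    noisy <- truth
    if (noiseSd > 0)
      noisy <- truth + rnorm(length(truth), sd = noiseSd * mean(truth))
    idx <- cbind(rep(seq_len(rows), each = cols),
                 rep(seq_len(cols), times = rows))
    toCube <- function(M) {
      arr <- array(0, c(rows, cols, length(wavelengths)))
      for (b in seq_len(ncol(M))) {
        m <- matrix(0, rows, cols)
        m[idx] <- M[, b]
        arr[, , b] <- m
      }
      Hypercube(arr, wavelengths)
    }
    reflectance <- toCube(noisy)
    noiseFree <- toCube(truth)

    gain <- .smoothField(rows, cols, 10, 0.9, 1.1)
    lamp <- 0.8 + 0.4 * sin(seq(0, pi, length.out = length(wavelengths)))
    darkLevel <- 100
    whiteArr <- array(0, c(rows, cols, length(wavelengths)))
    for (b in seq_along(wavelengths))
      whiteArr[, , b] <- darkLevel + 3000 * gain * lamp[b]
    white <- Hypercube(whiteArr, wavelengths, meta = list(role = "white"))
    dark <- Hypercube(array(darkLevel, dim(whiteArr)), wavelengths,
                      meta = list(role = "dark"))
    raw <- Hypercube(reflectance@values * (whiteArr - darkLevel) + darkLevel,
                     wavelengths, meta = list(role = "raw"))
    list(raw = raw, white = white, dark = dark, reflectance = reflectance,
         noiseFree = noiseFree, C = C, S = S,
         endmemberNames = vapply(endmembers, `[[`, character(1), "name"))
  })
}

#' Generate the synthetic concentration series
#'
#' Emulates the quantification study design: `length(levels) *
#' leavesPerLevel * roisPerLeaf` mean spectra (default 4 levels x 15
#' leaves x 2 ROIs = 120 observations). Each ROI mean spectrum is
#'
#' `leafScale * (leaf + responseCoef * y * residue) + noise`
#'
#' where `leafScale = 1 + N(0, leafEffectSd)` is a leaf-level
#' multiplicative scatter shared by both ROIs of a leaf (so group-aware
#' splitting matters) and the noise SD is `noiseSd` times the mean
#' signal.
#'
#' @param levels concentration levels in percent (default 0, 0.02, 0.04,
#'   0.06).
#' @param leavesPerLevel leaves sprayed per level (default 15).
#' @param roisPerLeaf regions of interest per leaf (default 2).
#' @param responseCoef linear response: residue abundance per percent
#'   concentration (default 5, i.e. abundance 0.3 at the 0.06% top
#'   level).
#' @param noiseSd spectral noise SD as fraction of mean signal (default
#'   0.01).
#' @param leafEffectSd SD of the leaf-level multiplicative scatter
#'   (default 0.02; set 0 for oracle tests).
#' @param wavelengths generation grid (default the full 274-band grid).
#' @param range working wavelength window kept in the output, inclusive
#'   (default 918-2058 nm); NULL keeps all bands.
#' @param endmembers list with `leaf` and residue [endmemberSpec()]s.
#' @param seed integer seed.
#' @return A [SpectralDataset-class] with one group id per leaf.
#' @export
makeConcentrationSeries <- function(levels = c(0, 0.02, 0.04, 0.06),
                                    leavesPerLevel = 15, roisPerLeaf = 2,
                                    responseCoef = 5, noiseSd = 0.01,
                                    leafEffectSd = 0.02,
                                    wavelengths = defaultWavelengths(),
                                    range = c(918, 2058),
                                    endmembers = defaultEndmembers()[
                                      c("leaf", "chlorfenapyr")],
                                    seed = 1) {
  if (length(levels) < 2) stop("at least two levels required", call. = FALSE)
  if (leavesPerLevel < 1) stop("leavesPerLevel must be >= 1", call. = FALSE)
  leafS <- makeEndmember(endmembers[[1]], wavelengths)
  resS <- makeEndmember(endmembers[[2]], wavelengths)
  meanSignal <- mean(leafS)
  withSeed(seed, {
    rows <- list(); y <- numeric(0); groups <- character(0)
    for (lv in levels) {
      for (leaf in seq_len(leavesPerLevel)) {
        gid <- sprintf("L%g_%02d", lv, leaf)
        leafScale <- 1 + rnorm(1, sd = leafEffectSd)
        for (roi in seq_len(roisPerLeaf)) {
          sp <- leafScale * (leafS + responseCoef * lv * resS)
          if (noiseSd > 0)
            sp <- sp + rnorm(length(sp), sd = noiseSd * meanSignal)
          rows[[length(rows) + 1L]] <- sp
          y <- c(y, lv)
          groups <- c(groups, gid)
        }
      }
    }
    X <- do.call(rbind, rows)
    if (!is.null(range)) {
      keep <- wavelengths >= range[1] & wavelengths <= range[2]
      X <- X[, keep, drop = FALSE]
      wavelengths <- wavelengths[keep]
    }
    SpectralDataset(X, y, wavelengths, groups)
  })
}

#' Write pure reference spectra as two-column text
#'
#' One file per endmember: whitespace-separated `wavelength reflectance`
#' rows, readable back with [readReferenceSpectrum()].
#'
#' @param endmembers named list of [endmemberSpec()]s.
#' @param wavelengths evaluation grid.
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, named by endmember.
#' @export
makeReferenceSpectra <- function(endmembers,
                                 wavelengths = defaultWavelengths(),
                                 dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(endmembers), function(nm) {
    s <- makeEndmember(endmembers[[nm]], wavelengths)
    p <- file.path(dir, paste0("reference_", nm, ".txt"))
    write.table(data.frame(wavelength = formatC(wavelengths, digits = 17,
                                                format = "g"),
                           reflectance = formatC(s, digits = 17,
                                                 format = "g")),
                p, row.names = FALSE, col.names = FALSE, quote = FALSE)
    p
  }, character(1))
  paths
}

#' Read a two-column reference spectrum
#'
#' @param path file of whitespace-separated `wavelength reflectance` rows.
#' @param wavelengths optional target grid; when the file grid differs,
#'   the spectrum is linearly interpolated onto it and the result carries
#'   attribute `interpolated = TRUE`.
#' @return Numeric spectrum with attribute `wavelengths` (and
#'   `interpolated` flag).
#' @export
readReferenceSpectrum <- function(path, wavelengths = NULL) {
  tab <- read.table(path, col.names = c("wavelength", "reflectance"))
  w <- tab$wavelength; s <- tab$reflectance
  interpolated <- FALSE
  if (!is.null(wavelengths) && !isTRUE(all.equal(w, wavelengths))) {
    s <- approx(w, s, xout = wavelengths, rule = 2)$y
    w <- wavelengths
    interpolated <- TRUE
  }
  structure(s, wavelengths = w, interpolated = interpolated)
}
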