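#' Reflectance calibration against white and dark references
#'
#' Converts raw counts to relative reflectance with the standard two-point
#' correction \eqn{R = (I_{raw} - I_{dark}) / (I_{white} - I_{dark})},
#' applied elementwise per pixel and band. Values outside [0, 1] are kept
#' (clipping would bias downstream unmixing); a warning is issued when any
#' value falls outside [-0.05, 1.05].
#'
#' @param raw,white,dark [Hypercube-class] objects sharing dimensions and
#'   wavelength axes: the sample scan, the white-reference scan and the
#'   dark-current scan.
#' @return A reflectance [Hypercube-class]; `meta(x)$calibration` records
#'   the correction.
#' @examples
#' w <- c(1000, 1100)
#' mk <- function(v) Hypercube(array(v, c(1, 1, 2)), w)
#' cubeValues(calibrateReflectance(mk(60), mk(100), mk(20)))  # 0.5
#' @export
calibrateReflectance <- function(raw, white, dark) {
  stopifnot(is(raw, "Hypercube"), is(white, "Hypercube"), is(dark, "Hypercube"))
  if (!identical(dim(raw@values), dim(white@values)) ||
      !identical(dim(raw@values), dim(dark@values)))
    stop("calibration cubes must share dimensions", call. = FALSE)
  if (!isTRUE(all.equal(raw@wavelengths, white@wavelengths)) ||
      !isTRUE(all.equal(raw@wavelengths, dark@wavelengths)))
    stop("calibration cubes must share the wavelength axis", call. = FALSE)
  denom <- white@values - dark@values
  if (any(denom == 0)) {
    bad <- which(apply(denom == 0, 3L, any))
    stop(sprintf(
      "degenerate reference: white - dark is zero at band %d (%.1f nm)",
      bad[1], raw@wavelengths[bad[1]]), call. = FALSE)
  }
  refl <- (raw@values - dark@values) / denom
  if (any(refl < -0.05) || any(refl > 1.05))
    warning("reflectance outside [-0.05, 1.05]; values kept unclipped",
            call. = FALSE)
  Hypercube(refl, raw@wavelengths,
            meta = c(raw@meta, list(calibration = "white/dark reflectance")))
}

#' Crop a cube to a wavelength window
#'
#' Retains bands with `lo <= lambda <= hi` (inclusive on both ends), in
#' their original order. The working range used for residue quantification
#' is 918-2058 nm.
#'
#' @param cube a [Hypercube-class].
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return The cropped [Hypercube-class].
#' @export
cropWavelengths <- function(cube, lo, hi) {
  stopifnot(is(cube, "Hypercube"))
  if (!(lo < hi)) stop("'lo' must be less than 'hi'", call. = FALSE)
  keep <- cube@wavelengths >= lo & cube@wavelengths <= hi
  if (!any(keep))
    stop(sprintf("empty range: no bands within [%g, %g] nm", lo, hi),
         call. = FALSE)
  Hypercube(cube@values[, , keep, drop = FALSE], cube@wavelengths[keep],
            meta = cube@meta)
}

#' Unfold a cube into a pixels-by-bands data matrix
#'
#' Rows are pixels in row-major scan order (row 1 left to right, then row
#' 2, ...), optionally restricted to a region of interest. The stored pixel
#' index makes refolding exact.
#'
#' @param cube a [Hypercube-class].
#' @param roi optional [RoiMask-class] matching the cube's spatial dims.
#' @return A [DataMatrix-class].
#' @export
unfold <- function(cube, roi = NULL) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@values)
  if (is.null(roi)) {
    mask <- matrix(TRUE, d[1], d[2])
  } else {
    stopifnot(is(roi, "RoiMask"))
    if (!identical(dim(roi@mask), d[1:2]))
      stop("roi does not match cube spatial dimensions", call. = FALSE)
    mask <- roi@mask
  }
  if (!any(mask)) stop("empty selection: roi has no pixels", call. = FALSE)
  sel <- which(mask, arr.ind = TRUE)
  sel <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]  # row-major scan
  nb <- d[3L]
  D <- vapply(seq_len(nb),
              function(b) cube@values[, , b][sel],
              numeric(nrow(sel)))
  D <- matrix(D, nrow = nrow(sel), ncol = nb)
  DataMatrix(D, sel, cube@wavelengths, d[1:2])
}

#' Refold per-pixel values into a spatial map
#'
#' Inverse of [unfold()] for a single per-pixel vector (an abundance
#' column, a residual norm, ...). Unselected positions are `NA`.
#'
#' @param values numeric vector, one value per indexed pixel.
#' @param pixelIndex integer matrix of (row, col), as stored in a
#'   [DataMatrix-class], or the DataMatrix itself.
#' @param spatialDims target (rows, cols); taken from the DataMatrix when
#'   one is supplied.
#' @return Numeric matrix map with `NA` at unselected positions.
#' @export
refold <- function(values, pixelIndex, spatialDims = NULL) {
  if (is(pixelIndex, "DataMatrix")) {
    spatialDims <- pixelIndex@spatialDims
    pixelIndex <- pixelIndex@pixelIndex
  }
  if (length(values) != nrow(pixelIndex))
    stop("length(values) must equal the number of indexed pixels",
         call. = FALSE)
  m <- matrix(NA_real_, spatialDims[1], spatialDims[2])
  m[pixelIndex] <- values
  m
}

#' Refold a full DataMatrix back into a Hypercube
#'
#' Exact inverse of [unfold()] when the whole image was unfolded;
#' unselected pixels are NA-filled otherwise (such cubes fail the
#' finiteness validity check, so partial refolds return a plain array).
#'
#' @param dm a [DataMatrix-class].
#' @return A [Hypercube-class] when complete, otherwise a 3-D array.
#' @export
refoldCube <- function(dm) {
  stopifnot(is(dm, "DataMatrix"))
  d <- c(dm@spatialDims, ncol(dm@D))
  arr <- array(NA_real_, d)
  for (b in seq_len(d[3L])) {
    m <- matrix(NA_real_, d[1L], d[2L])
    m[dm@pixelIndex] <- dm@D[, b]
    arr[, , b] <- m
  }
  if (all(is.finite(arr))) Hypercube(arr, dm@wavelengths) else arr
}

# ---- cube I/O --------------------------------------------------------------

.parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  getScalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key,
                                        "\\s*=\\s*([^\\n{]+)"), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  getList <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?smi)", key,
                                        "\\s*=\\s*\\{(.*?)\\}"), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(gsub("\\s", "", m[2]), ",")[[1]])
  }
  list(samples = as.integer(getScalar("samples")),
       lines = as.integer(getScalar("lines")),
       bands = as.integer(getScalar("bands")),
       dataType = as.integer(getScalar("data type")),
       interleave = tolower(getScalar("interleave")),
       byteOrder = as.integer(getScalar("byte order")),
       wavelength = getList("wavelength"))
}

#' Read a hyperspectral cube
#'
#' Two dialects are supported: ENVI header + binary with BIL (band
#' interleaved by line) layout, and a portable plain-text fallback (one CSV
#' holding the row-major unfolded values with explicit pixel coordinates,
#' plus a CSV wavelength list).
#'
#' @param path for `"envi"`, the binary file path (`<path>.hdr` must
#'   exist); for `"array+csv"`, a stem: `<stem>_values.csv` and
#'   `<stem>_wavelengths.csv` are read.
#' @param format `"envi"` or `"array+csv"`.
#' @return A [Hypercube-class].
#' @seealso [writeCube()]
#' @export
readCube <- function(path, format = c("envi", "array+csv")) {
  format <- match.arg(format)
  if (format == "envi") {
    hdrPath <- paste0(path, ".hdr")
    if (!file.exists(hdrPath)) stop("missing ENVI header: ", hdrPath,
                                    call. = FALSE)
    h <- .parseEnviHeader(hdrPath)
    if (is.null(h$wavelength))
      stop("format error: ENVI header has no wavelength list", call. = FALSE)
    if (length(h$wavelength) != h$bands)
      stop("format error: header declares ", h$bands, " bands but ",
           length(h$wavelength), " wavelengths", call. = FALSE)
    if (!identical(h$interleave, "bil"))
      stop("only BIL interleave is supported", call. = FALSE)
    n <- h$samples * h$lines * h$bands
    sz <- if (h$dataType == 4L) 4L else if (h$dataType == 5L) 8L else
      stop("unsupported ENVI data type ", h$dataType, call. = FALSE)
    endian <- if (identical(h$byteOrder, 1L)) "big" else "little"
    raw <- readBin(path, "numeric", n = n, size = sz, endian = endian)
    if (length(raw) != n) stop("truncated ENVI binary", call. = FALSE)
    # BIL: samples fastest, then bands, then lines
    arr <- aperm(array(raw, c(h$samples, h$bands, h$lines)), c(3, 1, 2))
    Hypercube(arr, h$wavelength, meta = list(source = path, format = "envi"))
  } else {
    vals <- read.csv(paste0(path, "_values.csv"), check.names = FALSE)
    w <- read.csv(paste0(path, "_wavelengths.csv"))$wavelength
    if (is.null(w)) stop("format error: missing wavelength list",
                         call. = FALSE)
    nb <- ncol(vals) - 2L
    if (nb != length(w))
      stop("format error: ", nb, " band columns but ", length(w),
           " wavelengths", call. = FALSE)
    rows <- max(vals$row); cols <- max(vals$col)
    arr <- array(NA_real_, c(rows, cols, nb))
    idx <- cbind(vals$row, vals$col)
    for (b in seq_len(nb)) {
      m <- matrix(NA_real_, rows, cols)
      m[idx] <- vals[[b + 2L]]
      arr[, , b] <- m
    }
    Hypercube(arr, w, meta = list(source = path, format = "array+csv"))
  }
}

#' Write a hyperspectral cube
#'
#' ENVI output uses 32-bit floats in BIL layout (round trips within float
#' precision); the `"array+csv"` dialect writes decimal text with 17
#' significant digits and round trips exactly.
#'
#' @param cube a [Hypercube-class].
#' @inheritParams readCube
#' @return `path`, invisibly.
#' @export
writeCube <- function(cube, path, format = c("envi", "array+csv")) {
  stopifnot(is(cube, "Hypercube"))
  format <- match.arg(format)
  d <- dim(cube@values)
  if (format == "envi") {
    hdr <- c("ENVI",
             paste0("samples = ", d[2]),
             paste0("lines = ", d[1]),
             paste0("bands = ", d[3]),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 4",
             "interleave = bil",
             "byte order = 0",
             paste0("wavelength = {",
                    paste(format(cube@wavelengths, digits = 10),
                          collapse = ", "), "}"))
    writeLines(hdr, paste0(path, ".hdr"))
    # BIL: for each line, band-by-band rows of samples
    v <- as.vector(aperm(cube@values, c(2, 3, 1)))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(v, con, size = 4L, endian = "little")
  } else {
    dm <- unfold(cube)
    chr <- formatC(dm@D, digits = 17, format = "g")
    out <- cbind(data.frame(row = dm@pixelIndex[, 1],
                            col = dm@pixelIndex[, 2]),
                 as.data.frame(chr, stringsAsFactors = FALSE))
    names(out) <- c("row", "col",
                    paste0("wl_", format(cube@wavelengths, digits = 10,
                                         trim = TRUE)))
    write.csv(out, paste0(path, "_values.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(data.frame(wavelength = formatC(cube@wavelengths, digits = 17,
                                              format = "g")),
              paste0(path, "_wavelengths.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}

#' Export a spatial map as CSV
#'
#' @param map numeric matrix (e.g. a refolded abundance map).
#' @param path output file.
#' @export
writeMapCSV <- function(map, path) {
  write.table(map, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render an abundance map to PNG
#'
#' Background (NA) pixels are drawn as zero-valued dark background, the
#' convention used for residue distribution maps.
#'
#' @param map numeric matrix.
#' @param path output PNG path.
#' @param main plot title.
#' @export
plotAbundanceMap <- function(map, path = NULL, main = "abundance") {
  draw <- function() {
    m <- map
    m[!is.finite(m)] <- 0
    graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                    col = grDevices::hcl.colors(64, "viridis"),
                    axes = FALSE, main = main)
  }
  if (is.null(path)) {
    draw()
  } else {
    grDevices::png(path, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}
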