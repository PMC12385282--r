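#' Hypercube: a hyperspectral image stack
#'
#' A 3-D reflectance (or raw-count) array of `rows x cols x bands` with a
#' strictly increasing wavelength axis in nanometres and free-form
#' provenance metadata. This is the object every pipeline stage consumes.
#'
#' @slot values 3-D numeric array, `rows x cols x bands`; all finite.
#' @slot wavelengths numeric vector of band centres in nm, strictly
#'   increasing, length equal to the band dimension.
#' @slot meta named list of provenance (source file, calibration state, ...).
#'
#' @exportClass Hypercube
setClass("Hypercube",
  representation(values = "array", wavelengths = "numeric", meta = "list"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 3L)
      return("'values' must be a 3-D array (rows x cols x bands)")
    if (!all(is.finite(v)))
      return("'values' must be finite everywhere")
    w <- object@wavelengths
    if (length(w) != dim(v)[3L])
      return("length(wavelengths) must equal the band dimension")
    if (length(w) > 1L && any(diff(w) <= 0))
      return("'wavelengths' must be strictly increasing")
    TRUE
  }
)

#' Construct a Hypercube
#'
#' @param values 3-D numeric array (rows x cols x bands).
#' @param wavelengths band centres in nm, strictly increasing.
#' @param meta named list of provenance entries.
#' @return A [Hypercube-class] object.
#' @examples
#' cube <- Hypercube(array(runif(2 * 3 * 4), c(2, 3, 4)),
#'                   wavelengths = c(1000, 1100, 1200, 1300))
#' dim(cube)
#' @export
Hypercube <- function(values, wavelengths, meta = list()) {
  new("Hypercube", values = values, wavelengths = as.numeric(wavelengths),
      meta = meta)
}

#' DataMatrix: an unfolded hypercube
#'
#' Pixels-by-bands matrix `D` obtained by unfolding a [Hypercube-class] in
#' row-major scan order, together with the spatial index needed to refold
#' per-pixel results (abundances, residuals) into maps.
#'
#' @slot D numeric matrix, `n_pixels x n_bands`.
#' @slot pixelIndex integer matrix, `n_pixels x 2` of (row, col), all unique.
#' @slot wavelengths numeric vector of nm, length `n_bands`.
#' @slot spatialDims integer vector, the (rows, cols) of the source cube.
#'
#' @exportClass DataMatrix
setClass("DataMatrix",
  representation(D = "matrix", pixelIndex = "matrix",
                 wavelengths = "numeric", spatialDims = "integer"),
  validity = function(object) {
    if (nrow(object@pixelIndex) != nrow(object@D))
      return("pixelIndex must have one row per pixel row of D")
    if (ncol(object@pixelIndex) != 2L)
      return("pixelIndex must have two columns (row, col)")
    if (anyDuplicated(object@pixelIndex))
      return("pixel indices must be unique")
    if (length(object@wavelengths) != ncol(object@D))
      return("length(wavelengths) must equal ncol(D)")
    if (length(object@spatialDims) != 2L)
      return("spatialDims must be (rows, cols)")
    TRUE
  }
)

DataMatrix <- function(D, pixelIndex, wavelengths, spatialDims) {
  new("DataMatrix", D = D,
      pixelIndex = matrix(as.integer(pixelIndex), ncol = 2L,
                          dimnames = list(NULL, c("row", "col"))),
      wavelengths = as.numeric(wavelengths),
      spatialDims = as.integer(spatialDims))
}

#' RoiMask: a region-of-interest mask
#'
#' Logical image mask matching a cube's spatial dimensions, with at least
#' one selected pixel.
#'
#' @slot mask logical matrix (rows x cols).
#' @slot label character label for the region.
#'
#' @exportClass RoiMask
setClass("RoiMask",
  representation(mask = "matrix", label = "character"),
  validity = function(object) {
    if (!is.logical(object@mask))
      return("'mask' must be a logical matrix")
    if (!any(object@mask))
      return("mask must select at least one pixel")
    TRUE
  }
)

#' @param mask logical matrix.
#' @param label region label.
#' @rdname RoiMask-class
#' @export
RoiMask <- function(mask, label = "roi") {
  new("RoiMask", mask = mask, label = label)
}

#' MCRResult: a fitted bilinear unmixing model
#'
#' Result of constrained MCR-ALS: abundances `C` (pixels x components),
#' resolved spectra `S` (components x bands), lack of fit, explained
#' variance, and the per-sweep LOF trace.
#'
#' @slot C numeric matrix of abundances, `n_pixels x k`.
#' @slot S numeric matrix of resolved spectra, `k x n_bands`.
#' @slot lofPercent lack of fit, percent.
#' @slot r2Percent explained variance, percent.
#' @slot nIter number of alternating sweeps performed.
#' @slot converged logical; whether the relative-LOF criterion was met.
#' @slot lofTrace per-sweep LOF values, percent.
#' @slot wavelengths band centres in nm for the columns of `S`.
#' @slot meta list: initialization used, constraint flags, ridge fallbacks.
#'
#' @exportClass MCRResult
setClass("MCRResult",
  representation(C = "matrix", S = "matrix", lofPercent = "numeric",
                 r2Percent = "numeric", nIter = "integer",
                 converged = "logical", lofTrace = "numeric",
                 wavelengths = "numeric", meta = "list"),
  prototype = list(C = matrix(numeric(0), 0, 0),
                   S = matrix(numeric(0), 0, 0), lofPercent = numeric(0),
                   r2Percent = numeric(0), nIter = 0L, converged = FALSE,
                   lofTrace = numeric(0), wavelengths = numeric(0),
                   meta = list()),
  validity = function(object) {
    if (ncol(object@C) != nrow(object@S))
      return("ncol(C) must equal nrow(S)")
    if (length(object@wavelengths) != ncol(object@S))
      return("length(wavelengths) must equal ncol(S)")
    if (length(object@lofPercent) == 1L && length(object@r2Percent) == 1L) {
      id <- 100 * (1 - (object@lofPercent / 100)^2)
      if (abs(id - object@r2Percent) > 1e-9)
        return("R2/LOF identity violated beyond 1e-9")
    }
    TRUE
  }
)

# Internal constructor: slot-wise assignment because a `C =` tag in new()
# would partially match its `Class` formal.
.MCRResult <- function(C, S, lofPercent, r2Percent, nIter, converged,
                       lofTrace, wavelengths, meta) {
  obj <- new("MCRResult")
  obj@C <- C; obj@S <- S
  obj@lofPercent <- lofPercent; obj@r2Percent <- r2Percent
  obj@nIter <- as.integer(nIter); obj@converged <- converged
  obj@lofTrace <- lofTrace; obj@wavelengths <- wavelengths
  obj@meta <- meta
  validObject(obj)
  obj
}

#' SpectralDataset: extracted mean spectra with concentration labels
#'
#' The regression table: one mean reflectance spectrum per region of
#' interest, its residue concentration in percent, and the leaf (group)
#' identity used for leakage-free splits.
#'
#' @slot X numeric matrix, `n x d` mean spectra.
#' @slot y numeric vector of concentrations in percent.
#' @slot wavelengths numeric d-vector of nm.
#' @slot groups character vector; rows from the same leaf share a value.
#'
#' @exportClass SpectralDataset
setClass("SpectralDataset",
  representation(X = "matrix", y = "numeric", wavelengths = "numeric",
                 groups = "character"),
  validity = function(object) {
    n <- nrow(object@X)
    if (length(object@y) != n) return("length(y) must equal nrow(X)")
    if (length(object@groups) != n) return("one group id per row required")
    if (length(object@wavelengths) != ncol(object@X))
      return("length(wavelengths) must equal ncol(X)")
    if (!all(is.finite(object@X)) || !all(is.finite(object@y)))
      return("X and y must be finite (no missing values)")
    TRUE
  }
)

#' @param X spectra matrix (rows = observations).
#' @param y concentrations in percent.
#' @param wavelengths band centres in nm.
#' @param groups leaf identifiers, one per row.
#' @rdname SpectralDataset-class
#' @export
SpectralDataset <- function(X, y, wavelengths, groups) {
  new("SpectralDataset", X = as.matrix(X), y = as.numeric(y),
      wavelengths = as.numeric(wavelengths), groups = as.character(groups))
}

#' RegressionReport: metrics for one concentration model
#'
#' Calibration and held-out (double cross-validation) performance of a
#' regression model, its predictions, the chosen kernel (for GPR) and the
#' ICH limit of detection.
#'
#' @slot modelName character, e.g. "GPR", "PLSR", "SVR".
#' @slot r2Cal,rmseCal calibration R-squared and RMSE (%).
#' @slot r2Val,rmseVal held-out R-squared and RMSE (%).
#' @slot predictions list with data.frames `calibration` and `test`
#'   (columns reference, predicted).
#' @slot chosenKernel character; kernel family (GPR) or model settings.
#' @slot lodPercent limit of detection in percent.
#'
#' @exportClass RegressionReport
setClass("RegressionReport",
  representation(modelName = "character", r2Cal = "numeric",
                 rmseCal = "numeric", r2Val = "numeric", rmseVal = "numeric",
                 predictions = "list", chosenKernel = "character",
                 lodPercent = "numeric"),
  validity = function(object) {
    if (length(object@rmseCal) && object@rmseCal < 0) return("rmseCal < 0")
    if (length(object@rmseVal) && object@rmseVal < 0) return("rmseVal < 0")
    if (length(object@r2Cal) && object@r2Cal > 1 + 1e-12) return("r2Cal > 1")
    if (length(object@r2Val) && object@r2Val > 1 + 1e-12) return("r2Val > 1")
    TRUE
  }
)
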