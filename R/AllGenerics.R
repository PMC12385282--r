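#' @describeIn Hypercube-class wavelength axis accessor
#' @param object,x an object with a wavelength axis
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @export
setMethod("wavelengths", "Hypercube", function(object) object@wavelengths)
#' @export
setMethod("wavelengths", "DataMatrix", function(object) object@wavelengths)
#' @export
setMethod("wavelengths", "MCRResult", function(object) object@wavelengths)
#' @export
setMethod("wavelengths", "SpectralDataset", function(object) object@wavelengths)

#' @describeIn Hypercube-class the raw value array
#' @export
setGeneric("cubeValues", function(object) standardGeneric("cubeValues"))
#' @export
setMethod("cubeValues", "Hypercube", function(object) object@values)

#' @describeIn Hypercube-class provenance metadata
#' @export
setGeneric("meta", function(object) standardGeneric("meta"))
#' @export
setMethod("meta", "Hypercube", function(object) object@meta)
#' @export
setMethod("meta", "MCRResult", function(object) object@meta)

#' @export
setMethod("dim", "Hypercube", function(x) dim(x@values))

#' @describeIn DataMatrix-class the unfolded pixels-by-bands matrix
#' @export
setGeneric("dataMatrix", function(object) standardGeneric("dataMatrix"))
#' @export
setMethod("dataMatrix", "DataMatrix", function(object) object@D)

#' @describeIn DataMatrix-class ordered (row, col) scan index
#' @export
setGeneric("pixelIndex", function(object) standardGeneric("pixelIndex"))
#' @export
setMethod("pixelIndex", "DataMatrix", function(object) object@pixelIndex)

#' @describeIn MCRResult-class abundance matrix C (pixels x components)
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))
#' @export
setMethod("abundances", "MCRResult", function(object) object@C)

#' @describeIn MCRResult-class resolved spectra S (components x bands)
#' @export
setGeneric("resolvedSpectra", function(object) standardGeneric("resolvedSpectra"))
#' @export
setMethod("resolvedSpectra", "MCRResult", function(object) object@S)

#' @describeIn MCRResult-class lack of fit, percent
#' @export
setGeneric("lofPercent", function(object) standardGeneric("lofPercent"))
#' @export
setMethod("lofPercent", "MCRResult", function(object) object@lofPercent)

#' @describeIn MCRResult-class explained variance, percent
#' @export
setGeneric("r2Percent", function(object) standardGeneric("r2Percent"))
#' @export
setMethod("r2Percent", "MCRResult", function(object) object@r2Percent)

#' @describeIn MCRResult-class per-sweep lack-of-fit trace
#' @export
setGeneric("lofTrace", function(object) standardGeneric("lofTrace"))
#' @export
setMethod("lofTrace", "MCRResult", function(object) object@lofTrace)

#' @describeIn MCRResult-class whether the relative-LOF criterion was met
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @export
setMethod("isConverged", "MCRResult", function(object) object@converged)

#' @describeIn MCRResult-class number of alternating sweeps run
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))
#' @export
setMethod("nIterations", "MCRResult", function(object) object@nIter)

#' @describeIn SpectralDataset-class spectra matrix accessor
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))
#' @export
setMethod("spectra", "SpectralDataset", function(object) object@X)

#' @describeIn SpectralDataset-class concentration labels, percent
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @export
setMethod("concentrations", "SpectralDataset", function(object) object@y)

#' @describeIn SpectralDataset-class leaf/group identifiers
#' @export
setGeneric("groupIds", function(object) standardGeneric("groupIds"))
#' @export
setMethod("groupIds", "SpectralDataset", function(object) object@groups)

#' @export
setMethod("dim", "SpectralDataset", function(x) dim(x@X))

#' @export
setMethod("show", "Hypercube", function(object) {
  d <- dim(object@values)
  w <- object@wavelengths
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(w), max(w)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

#' @export
setMethod("show", "DataMatrix", function(object) {
  cat(sprintf("DataMatrix: %d pixels x %d bands (source %d x %d)\n",
              nrow(object@D), ncol(object@D),
              object@spatialDims[1], object@spatialDims[2]))
})

#' @export
setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask '%s': %d of %d pixels selected\n", object@label,
              sum(object@mask), length(object@mask)))
})

#' @export
setMethod("show", "MCRResult", function(object) {
  cat(sprintf("MCRResult: %d components, %d pixels x %d bands\n",
              ncol(object@C), nrow(object@C), ncol(object@S)))
  cat(sprintf("  LOF = %.4g%%, explained variance = %.4g%%\n",
              object@lofPercent, object@r2Percent))
  cat(sprintf("  %d sweeps, converged: %s\n", object@nIter,
              object@converged))
})

#' @export
setMethod("show", "SpectralDataset", function(object) {
  cat(sprintf("SpectralDataset: %d spectra x %d bands, %d groups\n",
              nrow(object@X), ncol(object@X),
              length(unique(object@groups))))
  cat(sprintf("  concentrations (%%): %s\n",
              paste(sort(unique(object@y)), collapse = ", ")))
})

#' @export
setMethod("show", "RegressionReport", function(object) {
  cat(sprintf("RegressionReport [%s]\n", object@modelName))
  cat(sprintf("  calibration: R2 = %.4f, RMSE = %.5g%%\n",
              object@r2Cal, object@rmseCal))
  cat(sprintf("  validation:  R2 = %.4f, RMSE = %.5g%%\n",
              object@r2Val, object@rmseVal))
  if (length(object@chosenKernel) && nzchar(object@chosenKernel))
    cat(sprintf("  kernel/settings: %s\n", object@chosenKernel))
  if (length(object@lodPercent) && is.finite(object@lodPercent))
    cat(sprintf("  LOD = %.5g%%\n", object@lodPercent))
})
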