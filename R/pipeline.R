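#' Read a pipeline run configuration
#'
#' YAML configuration with defaults merged in. Recognised top-level keys:
#' `workflow` (detect / quantify / simulate), `seed`, `outputDir`,
#' `input` (paths to cubes or a series CSV), `scene` and `series`
#' (synthetic-generation settings), `mcr` (arguments of [mcrControl()]),
#' `crop` (two-element working range in nm), `split` (calFraction,
#' innerFolds, nRepeats), `topFraction`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged over the file contents.
#' @return Named list of class `RunConfig`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  defaults <- list(
    workflow = "simulate",
    seed = 1L,
    outputDir = "specres-output",
    logLevel = "info",
    input = list(),
    scene = list(rows = 64, cols = 64, pattern = "smooth", noiseSd = 0.01),
    series = list(),
    crop = c(918, 2058),
    mcr = list(nComponents = 2, init = "simplisma", tol = 0.1,
               maxIter = 10000),
    split = list(calFraction = 0.70, innerFolds = 5, nRepeats = 1),
    topFraction = 0.2,
    writePng = FALSE)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "RunConfig")
}

.configHash <- function(config) {
  rlang::hash(unclass(config))
}

.logMsg <- function(config, ...) {
  if (identical(config$logLevel, "quiet")) return(invisible())
  message(sprintf("[specres] %s", paste0(...)))
}

.writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Load or synthesize the raw/white/dark triplet named by the config.
.obtainScene <- function(config) {
  inp <- config$input
  if (!is.null(inp$raw)) {
    fmt <- if (is.null(inp$format)) "envi" else inp$format
    raw <- readCube(inp$raw, fmt)
    if (!is.null(inp$white)) {
      white <- readCube(inp$white, fmt)
      dark <- readCube(inp$dark, fmt)
      list(reflectance = calibrateReflectance(raw, white, dark))
    } else {
      list(reflectance = raw)      # already calibrated
    }
  } else {
    sc <- config$scene
    makeScene(rows = sc$rows %||% 64, cols = sc$cols %||% 64,
              pattern = sc$pattern %||% "smooth",
              noiseSd = sc$noiseSd %||% 0.01,
              seed = childSeed(config$seed, 1L))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the residue-detection workflow
#'
#' Calibrate (when references are supplied) or synthesize a scene, crop to
#' the working wavelength window, unfold, initialize (SIMPLISMA or
#' reference spectra), fit the constrained two-component MCR-ALS model,
#' and write resolved spectra, abundance maps, component proportions and
#' diagnostics to the output directory. Every report embeds the seed and
#' a hash of the configuration, so reruns are byte-reproducible.
#'
#' @param config a `RunConfig` from [readRunConfig()].
#' @return The report list, invisibly; artifacts under
#'   `config$outputDir`.
#' @export
runDetection <- function(config = readRunConfig()) {
  out <- config$outputDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  scene <- .obtainScene(config)
  cube <- if (!is.null(scene$reflectance)) scene$reflectance else
    calibrateReflectance(scene$raw, scene$white, scene$dark)
  if (!is.null(config$crop))
    cube <- cropWavelengths(cube, config$crop[1], config$crop[2])
  dm <- unfold(cube)

  mcrArgs <- config$mcr
  ctrl <- mcrControl(nComponents = mcrArgs$nComponents %||% 2,
                     init = mcrArgs$init %||% "simplisma",
                     tol = mcrArgs$tol %||% 0.1,
                     maxIter = mcrArgs$maxIter %||% 10000)
  refS <- NULL
  if (ctrl$init == "reference") {
    paths <- config$input$references
    if (is.null(paths)) stop("reference init requires input$references",
                             call. = FALSE)
    refS <- do.call(rbind, lapply(paths, function(p)
      as.numeric(readReferenceSpectrum(p, wavelengths(cube)))))
  }
  fit <- fitMCR(dm, ctrl, referenceSpectra = refS)
  props <- componentProportions(fit)

  writeResolvedSpectra(fit, file.path(out, "resolved_spectra.csv"))
  for (i in seq_len(ncol(abundances(fit)))) {
    map <- refold(abundances(fit)[, i], dm)
    writeMapCSV(map, file.path(out, sprintf("abundance_map_%d.csv", i)))
    if (isTRUE(config$writePng))
      plotAbundanceMap(map, file.path(out, sprintf("abundance_map_%d.png",
                                                   i)),
                       main = sprintf("component %d", i))
  }
  report <- list(workflow = "detect", seed = config$seed,
                 configHash = .configHash(config),
                 nComponents = ctrl$nComponents, init = ctrl$init,
                 lofPercent = lofPercent(fit), r2Percent = r2Percent(fit),
                 nIter = nIterations(fit), converged = isConverged(fit),
                 proportionsPercent = as.numeric(props))
  .writeReport(report, file.path(out, "detection_report.json"))
  .logMsg(config, sprintf("detection: LOF %.4g%%, R2 %.4g%%, %d sweeps",
                          report$lofPercent, report$r2Percent,
                          report$nIter))
  invisible(report)
}

# Per-leaf spectral extraction: MCR-ALS on each leaf cube, residue-region
# selection on the residue abundance map, one mean spectrum per ROI half.
.extractFromLeafCube <- function(cube, config, referenceResidue = NULL) {
  dm <- unfold(cube)
  ctrl <- mcrControl(nComponents = 2, init = "simplisma",
                     tol = config$mcr$tol %||% 0.1,
                     maxIter = config$mcr$maxIter %||% 10000)
  fit <- fitMCR(dm, ctrl)
  resIdx <- 2L
  if (!is.null(referenceResidue)) {
    resIdx <- matchComponents(fit, rbind(referenceResidue))[1L]
  }
  map <- refold(abundances(fit)[, resIdx], dm)
  half <- ncol(map) %/% 2
  leftMask <- matrix(FALSE, nrow(map), ncol(map))
  leftMask[, seq_len(half)] <- TRUE
  out <- lapply(list(left = leftMask, right = !leftMask), function(hm) {
    sub <- map
    sub[!hm] <- NA
    roi <- selectResidueRegions(sub, config$topFraction %||% 0.2)
    extractMeanSpectra(dm, roi)[1L, ]
  })
  do.call(rbind, out)
}

#' Run the quantification workflow
#'
#' Assembles the concentration-series regression table (from a series CSV
#' named in `config$input$series`, or synthesized via
#' [makeConcentrationSeries()]), performs the group-aware 70/30 outer
#' split with 5-fold inner selection for GPR, PLSR and SVR, and writes
#' per-model metrics, the relative-improvement table (GPR versus the best
#' baseline) and the ICH limit of detection.
#'
#' When `config$input$leafCubes` lists per-leaf reflectance cubes with
#' labels, the table is instead built by per-leaf MCR-ALS unmixing,
#' residue-region selection and mean-spectrum extraction (two ROIs per
#' leaf).
#'
#' @param config a `RunConfig`.
#' @return Report list, invisibly; artifacts under `config$outputDir`.
#' @export
runQuantification <- function(config = readRunConfig(
                                overrides = list(workflow = "quantify"))) {
  out <- config$outputDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  if (!is.null(config$input$series)) {
    ds <- readSpectralDataset(config$input$series)
  } else if (!is.null(config$input$leafCubes)) {
    lc <- config$input$leafCubes
    fmt <- config$input$format %||% "array+csv"
    rows <- list(); y <- numeric(0); groups <- character(0)
    for (i in seq_along(lc$paths)) {
      cube <- readCube(lc$paths[[i]], fmt)
      if (!is.null(config$crop))
        cube <- cropWavelengths(cube, config$crop[1], config$crop[2])
      sp <- .extractFromLeafCube(cube, config)
      rows[[i]] <- sp
      y <- c(y, rep(lc$labels[[i]], nrow(sp)))
      groups <- c(groups, rep(sprintf("leaf%03d", i), nrow(sp)))
    }
    X <- do.call(rbind, rows)
    ds <- SpectralDataset(X, y, wavelengths(cube), groups)
  } else {
    args <- config$series
    args$seed <- args$seed %||% childSeed(config$seed, 2L)
    ds <- do.call(makeConcentrationSeries, args)
  }

  sp <- config$split
  factories <- list(GPR = gprFactory(), PLSR = plsrFactory(),
                    SVR = svrFactory())
  reports <- list()
  for (nm in names(factories)) {
    dcv <- doubleCrossValidation(ds, factories[[nm]],
                                 calFraction = sp$calFraction %||% 0.70,
                                 innerFolds = sp$innerFolds %||% 5,
                                 nRepeats = sp$nRepeats %||% 1,
                                 seed = childSeed(config$seed, 3L))
    kern <- if (nm == "GPR") dcv$model$chosenKernel else ""
    reports[[nm]] <- .makeReport(dcv, nm, kern)
    .logMsg(config, sprintf("%s: R2v %.4f, RMSEV %.5g%%", nm,
                            dcv$r2Val, dcv$rmseVal))
  }

  metric <- function(r, what) slot(reports[[r]], what)
  bestBaselineRmse <- min(metric("PLSR", "rmseVal"), metric("SVR", "rmseVal"))
  bestBaselineR2 <- max(metric("PLSR", "r2Val"), metric("SVR", "r2Val"))
  improvements <- list(
    rmsevReductionPercent = relativeImprovement(
      bestBaselineRmse, metric("GPR", "rmseVal"), "lower-better"),
    r2vGainPercent = relativeImprovement(
      bestBaselineR2, metric("GPR", "r2Val"), "higher-better"))

  metricsTable <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, r2Cal = r@r2Cal, rmseCal = r@rmseCal,
               r2Val = r@r2Val, rmseVal = r@rmseVal,
               lodPercent = r@lodPercent, kernel = r@chosenKernel)
  }))
  write.csv(metricsTable, file.path(out, "model_metrics.csv"),
            row.names = FALSE)
  report <- list(workflow = "quantify", seed = config$seed,
                 configHash = .configHash(config),
                 n = nrow(spectra(ds)),
                 metrics = metricsTable,
                 improvements = improvements,
                 lodPercentGPR = reports$GPR@lodPercent)
  .writeReport(report, file.path(out, "quantification_report.json"))
  invisible(c(report, list(reports = reports, dataset = ds)))
}

#' Run the simulation workflow
#'
#' Generates one synthetic scene (raw/white/dark cubes) and one
#' concentration series, writes them to disk through the cube and
#' dataset writers, and records a manifest of seeds and specifications.
#' Two invocations with the same seed produce identical files.
#'
#' @param config a `RunConfig`.
#' @return Manifest list, invisibly.
#' @export
runSimulate <- function(config = readRunConfig()) {
  out <- config$outputDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  sc <- config$scene
  scene <- makeScene(rows = sc$rows %||% 64, cols = sc$cols %||% 64,
                     pattern = sc$pattern %||% "smooth",
                     noiseSd = sc$noiseSd %||% 0.01,
                     seed = childSeed(config$seed, 1L))
  fmt <- config$input$format %||% "array+csv"
  for (nm in c("raw", "white", "dark"))
    writeCube(scene[[nm]], file.path(out, paste0("scene_", nm)), fmt)

  args <- config$series
  args$seed <- args$seed %||% childSeed(config$seed, 2L)
  series <- do.call(makeConcentrationSeries, args)
  writeSpectralDataset(series, file.path(out, "series.csv"))

  manifest <- list(seed = config$seed,
                   configHash = .configHash(config),
                   scene = list(rows = sc$rows %||% 64,
                                cols = sc$cols %||% 64,
                                pattern = sc$pattern %||% "smooth",
                                noiseSd = sc$noiseSd %||% 0.01,
                                seed = childSeed(config$seed, 1L),
                                files = paste0("scene_",
                                               c("raw", "white", "dark"))),
                   series = list(n = nrow(spectra(series)),
                                 seed = args$seed, file = "series.csv"))
  .writeReport(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}

#' Write / read a SpectralDataset as CSV
#'
#' Layout: first column `group`, second `concentration` (percent), then
#' one column per wavelength (`wl_<nm>`).
#'
#' @param ds a [SpectralDataset-class].
#' @param path CSV path.
#' @return `path` (write) or the dataset (read).
#' @export
writeSpectralDataset <- function(ds, path) {
  stopifnot(is(ds, "SpectralDataset"))
  chr <- formatC(ds@X, digits = 17, format = "g")
  df <- cbind(data.frame(group = ds@groups,
                         concentration = formatC(ds@y, digits = 17,
                                                 format = "g")),
              as.data.frame(chr, stringsAsFactors = FALSE))
  names(df) <- c("group", "concentration",
                 paste0("wl_", format(ds@wavelengths, digits = 10,
                                      trim = TRUE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectralDataset
#' @export
readSpectralDataset <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- as.numeric(sub("^wl_", "", names(df)[-(1:2)]))
  SpectralDataset(as.matrix(df[, -(1:2)]), df$concentration, wl, df$group)
}
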