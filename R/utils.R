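# Evaluate an expression under a temporary RNG state. Keeps generator
# settings of the caller intact so seeded helpers compose predictably.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default SWIR wavelength grid
#'
#' The working spectrograph grid: 894 nm start, 5.876 nm resolution,
#' 274 bands (894-2498 nm).
#'
#' @return Numeric vector of band centres in nm.
#' @export
defaultWavelengths <- function() {
  seq(894, by = 5.876, length.out = 274)
}

# Deterministic child-seed spawning: all randomness in a pipeline run
# flows from one root seed through this map.
childSeed <- function(seed, i) {
  (as.integer(seed) + 7919L * as.integer(i)) %% 2147483629L
}
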