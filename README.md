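# specres

Hyperspectral unmixing and Gaussian-process quantification of surface
pesticide residues on leaves.

## What problem this solves

Pesticide residues on leafy vegetables (e.g. an insecticide such as
chlorfenapyr or a fungicide such as azoxystrobin on perilla leaves) are
conventionally quantified by destructive chromatography. Short-wave
infrared (SWIR, ~900–2500 nm) hyperspectral imaging sees the residues
non-destructively, but every pixel mixes the residue signal with the leaf
matrix. `specres` is an R package for analysts working with such data. It
implements the full chain:

1. **Calibration** — raw counts to reflectance,
   `R = (I_raw − I_dark) / (I_white − I_dark)`, with ENVI (BIL) and
   plain-text cube I/O.
2. **Unmixing** — multivariate curve resolution by alternating least
   squares (MCR-ALS) on the unfolded pixels-by-bands matrix,
   `D = C Sᵀ + E` with non-negativity on both abundances `C` and spectra
   `S`, exact active-set NNLS subproblem solves (compiled), SIMPLISMA
   pure-variable or reference-spectrum initialization, and the standard
   diagnostics `LOF = 100·√(Σe²/Σd²)` and `R² = 100·(Σd²−Σe²)/Σd²`.
3. **Quantification** — mean spectra of the highest-abundance residue
   regions regressed on concentration with Gaussian process regression
   (SE / Matérn 3/2 / Matérn 5/2 / rational-quadratic kernels,
   marginal-likelihood hyperparameters, kernel chosen by 5-fold inner CV)
   inside a group-aware 70/30 double cross-validation; PLSR and SVR
   baselines; ICH limit of detection `LOD = 3.3·ρ/S`.
4. **Statistics** — Mann–Whitney U comparisons of per-pixel abundance
   distributions between consecutive concentration levels.
5. **Synthetic scenes** — a generator for bilinear leaf+residue
   hypercubes and concentration series with known ground truth, so the
   entire pipeline is testable without camera data.

The methods vignette (`vignettes/residue-unmixing.Rmd`) documents the
models, the defaults and the design decisions in detail.

## Worked example

```r
library(specres)

# a 64 x 64 synthetic leaf scene with 1% noise, through calibration
sc   <- makeScene(rows = 64, cols = 64, noiseSd = 0.01, seed = 1)
cube <- calibrateReflectance(sc$raw, sc$white, sc$dark)
cube
#> Hypercube: 64 x 64 pixels, 274 bands (894.0-2498.1 nm)

# two-component constrained unmixing
fit <- fitMCR(unfold(cube), mcrControl(nComponents = 2))
fit
#> MCRResult: 2 components, 4096 pixels x 274 bands
#>   LOF = 0.9742%, explained variance = 99.99%
#>   2 sweeps, converged: TRUE
```

The lack of fit sits at the injected noise level (≈1% of signal) and the
bilinear model explains 99.99% of the variance — the residue and leaf
spectra are cleanly separated. Abundance maps come from
`refold(abundances(fit)[, i], dm)`.

```r
# the 120-spectrum concentration series (4 levels x 15 leaves x 2 ROIs)
ds <- makeConcentrationSeries(seed = 1, leafEffectSd = 0)
dcv <- doubleCrossValidation(ds, gprFactory(), seed = 1)
#> GPR held-out R2 = 0.9999, RMSEV = 0.000158%, kernel = matern52
lodFromCalibration(dcv$predictions$calibration$reference,
                   dcv$predictions$calibration$predicted)$lod
#> 1.51e-07
```

Held-out `R²` near 1 and an RMSEV of ~0.0002 percentage points mean the
GP recovers the 0–0.06% concentration ladder almost exactly at this noise
level; the near-zero LOD reflects the near-perfect calibration line of
the synthetic series.

End-to-end workflows (`runSimulate()`, `runDetection()`,
`runQuantification()`) are driven by a YAML `RunConfig` and write CSV/JSON
reports that embed the seed and a configuration hash.

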