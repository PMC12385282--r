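---
title: "Methods: SWIR unmixing and residue quantification with specres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SWIR unmixing and residue quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Surface pesticide residues on leafy vegetables absorb and reflect in the
short-wave infrared (SWIR, roughly 900-2500 nm) through O-H, C-H and N-H
overtone and combination bands. A line-scan SWIR camera turns a leaf into a
hypercube: a `rows x cols x bands` stack of reflectance spectra. The residue
signal is weak and everywhere mixed with the leaf matrix, so two statistical
problems arise:

1. **Unmixing** — separate every pixel's spectrum into a leaf component and
   a residue component, and map where the residue sits; and
2. **Quantification** — predict the applied concentration (in percent of
   active ingredient) from mean spectra of the residue-rich regions.

`specres` implements both stages plus the surrounding plumbing
(calibration, cube I/O, region selection, nonparametric comparisons) and a
synthetic-scene generator that makes the whole pipeline testable without
proprietary camera data.

# Reflectance calibration

Raw counts are converted to relative reflectance with the usual two-point
correction against a white reference (Teflon panel) and a dark-current
scan:

$$R = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}}.$$

The operation is elementwise; a zero `white - dark` denominator at any
band is an error that names the offending band. Values outside [0, 1] are
**kept, not clipped**: clipping would censor exactly the tails that the
bilinear model must explain, and would bias the non-negative least-squares
updates. A warning is raised past a small slack (±0.05) so gross
calibration failures still surface. No smoothing or scatter correction is
applied after the ratio; the unmixing model is expected to absorb smooth
multiplicative structure into the abundance maps.

# The bilinear model and MCR-ALS

The calibrated cube (cropped to the 918-2058 nm working window, 194 bands
on the instrument grid of 894 nm + k·5.876 nm) is unfolded in row-major
scan order into a pixels-by-bands matrix $D$, modelled as

$$D = C\,S + E,$$

with $C \ge 0$ the `pixels x k` abundance matrix, $S \ge 0$ the
`k x bands` matrix of component spectra, and $E$ the residual. For a leaf
with one residue, $k = 2$; the package's model-order probe (refit with
extra components and inspect their abundance shares) supports that choice
on synthetic scenes.

`fitMCR()` alternates exactly solved, conditionally optimal subproblems:
given $S$, every pixel row of $C$ is an active-set non-negative
least-squares (Lawson-Hanson) problem; given $C$, every band column of
$S$ is one too. The solver works on the normal equations (the component
count is small) and is implemented in compiled code because a 64 x 64
scene means 4096 independent NNLS problems per sweep. Because each
half-update is a constrained minimizer of the same objective, the
lack-of-fit trace is non-increasing by construction — this is what makes
the relative-change stopping rule meaningful.

Fit quality is reported as percent lack of fit and explained variance,

$$\mathrm{LOF} = 100\sqrt{\frac{\sum e_{ij}^2}{\sum d_{ij}^2}}, \qquad
R^2 = 100\,\frac{\sum d_{ij}^2 - \sum e_{ij}^2}{\sum d_{ij}^2},$$

which satisfy $R^2 = 100(1 - (\mathrm{LOF}/100)^2)$ identically; the
package enforces this identity to 1e-9 in the result class itself.

Numerical choices, all configurable through `mcrControl()`:

* **Convergence** — stop when the relative LOF change between consecutive
  sweeps falls below `tol` (default 0.1%), or after `maxIter` (default
  10000) sweeps, whichever comes first. LOF is the natural iterate-level
  diagnostic for this rule because it is the quantity the alternating
  solves monotonically reduce.
* **Scale ambiguity** — bilinear factorizations are only identified up to
  a positive diagonal rescaling. After every sweep each spectrum row is
  normalized to unit maximum and the inverse factor absorbed into the
  abundances. Reported component proportions (percent of total abundance
  mass) therefore depend on this convention; with a different
  normalization the same fit yields different proportions, which is why
  proportion values are comparable only within a convention.
* **Degeneracy** — a rank-deficient passive-set solve falls back to a
  tiny ridge (1e-10 of the mean normal-matrix diagonal) and the fit
  records how often that happened; a warning is emitted.

## Initialization

Two routes, matching the two use cases:

* **Reference spectra** (`init = "reference"`): pure-component spectra
  measured separately, interpolated onto the cube grid if needed
  (`readReferenceSpectrum()` flags interpolation).
* **SIMPLISMA** (`init = "simplisma"`): pure-variable selection when no
  references exist. Band purity is $p_j = \sigma_j/(\mu_j + \delta)$ with
  the offset $\delta$ set to 3% of the largest band mean by default (the
  conventional 1-5% range; larger offsets damp low-mean noise bands).
  Subsequent picks are weighted by the determinant of the
  correlation-around-origin submatrix of the candidate plus the already
  selected bands, which suppresses bands correlated with earlier picks.
  Initial spectra are resolved from the pure-variable intensity profiles
  by NNLS, which in the exact-bilinear case recovers the generating
  spectra up to scale.

## From maps to a regression table

The residue component is identified by correlation with the reference (or
initial) spectrum (`matchComponents()`). Its abundance vector is refolded
to image geometry, and `selectResidueRegions()` masks the top fraction
(default `topFraction = 0.2`) of pixels by abundance — the "highest
residue" regions; ties break by scan order so the mask is deterministic.
`extractMeanSpectra()` averages the masked pixels per band. In the study
design each leaf contributes two such regions (one per leaf half), so 60
leaves across four concentration levels yield the 120-row regression
table.

# Concentration regression

## Gaussian process regression

Concentrations are modelled as $y = g(x) + \eta$ with
$g \sim \mathcal{GP}(0, k(x, x'))$ and i.i.d. Gaussian noise $\eta$. The
zero-mean prior is reconciled with nonzero concentrations by centering:
the GP is fitted to $y - \bar y$ and $\bar y$ is added back at
prediction. Spectra are standardized per band using calibration
statistics only. Four isotropic kernel families are available — squared
exponential, Matérn 3/2, Matérn 5/2 and rational quadratic — each with
length scale, signal variance and noise variance (plus the RQ shape)
fitted by maximizing the Gaussian marginal likelihood with L-BFGS-B on
log-parameters. The marginal likelihood is multimodal, so five seeded
restarts are used, centred on data-driven heuristics (median pairwise
distance, label variance). The predictive mean and variance are the
standard conditionals $k_*^\top (K + \sigma^2 I)^{-1} y$ etc.; predictive
variances are clamped at zero after the Cholesky solve.

## Model selection and honest validation

Validation is a **double (nested) cross-validation**: the outer loop is a
group-aware stratified 70/30 split — whole leaves, never single spectra,
are allocated, so the two ROI spectra of one leaf can never straddle the
split. Within each concentration level the number of calibration leaves
uses largest-remainder rounding with leftovers assigned symmetrically
from the outermost levels inward; for the balanced, equally spaced
4 x 15-leaf design this yields 42 calibration leaves (84 spectra) and 18
test leaves (36 spectra) with both subset label means exactly 0.030%.
The inner loop is 5-fold (again group-aware) selection on the calibration
subset only: kernel family for GPR, latent-variable count for PLSR,
cost/gamma/epsilon for SVR. Ties in the inner score go to the simpler
kernel (menu order SE, Matérn 3/2, Matérn 5/2, RQ). Held-out $R^2_v$ and
$RMSE_v$ come from outer-test predictions alone. A single outer split
with a fixed seed is the default, matching a single reported test set;
`nRepeats` averages several outer splits when a tighter estimate is
wanted.

Baselines use the same interface: PLSR delegates to `mixOmics::pls`
(mean-centered, regression mode) and SVR to `e1071::svm` (RBF,
epsilon-regression, standardized spectra, grid `cost` 1e-2..1e3, `gamma`
1e-4..1e1, `epsilon` 1e-4..1e-2).

## Limit of detection

The ICH standard-deviation-of-the-response method:
$\mathrm{LOD} = 3.3\,\rho/S$, where $\rho$ is the residual standard
deviation and $S$ the slope of the ordinary regression of calibration
predictions on reference concentrations. The result is in concentration
percent; no conversion to ppm is attempted because that requires a mass
basis (spray deposition per leaf area) the spectra alone do not fix.

## Comparing models

`relativeImprovement()` expresses a metric change as percent of the
baseline: error-type metrics as $100(ref - new)/ref$, score-type as
$100(new - ref)/ref$. Applied to published-style metric tables (e.g.
RMSEV 0.0037% to 0.0012%, R²v 0.97 to 0.99) it returns 67.57% and 2.06%.

# Nonparametric comparison of abundance distributions

Per-pixel abundances are skewed, so adjacent concentration levels are
compared with the Mann-Whitney U test (`mannWhitneyU()`, a thin wrapper
over `stats::wilcox.test` that also reports the U count): exact null for
a smaller sample of at most 8 with tie-free data, otherwise the
tie-corrected normal approximation with continuity correction. The
two-sided alternative is the default (no direction is assumed), and
`consecutiveLevelTests()` applies no multiplicity correction — each
adjacent pair is reported at the nominal 0.05 level, as is conventional
for this design; the table makes the raw p-values available for any
correction the user prefers. Pixels are treated as exchangeable, which
ignores spatial autocorrelation; with thousands of correlated pixels the
effective sample size is smaller than the nominal one, so p-values should
be read qualitatively.

# The synthetic-scene generator

No leaf hypercubes are distributed with the instrument study this package
operationalizes, so `specres` ships a generator that emulates the
*statistical structure the analysis assumes*, and is itself first-class,
tested code:

* **Endmembers** (`makeEndmember()`): baseline plus signed Gaussian bands
  floored at zero. The built-in library places leaf bands at 1123, 1170,
  1300, 1450, 1652 nm and residue bands at 1141, 1217, 1394, 1558, 1860,
  1940 nm (chlorfenapyr-like) and 1217, 1394, 1623, 2030 nm
  (azoxystrobin-like), with the water features (1450, 1940 nm) as
  absorption dips. Widths of 15-40 nm keep neighbouring bands resolvable
  on the 5.876 nm grid while looking like realistic SWIR envelopes.
* **Scenes** (`makeScene()`): non-negative abundance fields (smoothed
  random fields, droplet-like blobs, or half-and-half), bilinear truth
  $CS$, additive Gaussian noise scaled to a fraction of the mean signal
  (default 1%), and a raw/white/dark triplet constructed so that
  reflectance calibration recovers the noisy truth exactly. The default
  64 x 64 x 274 scene fits in well under a second per MCR-ALS fit.
* **Concentration series** (`makeConcentrationSeries()`): four levels
  (0, 0.02, 0.04, 0.06%), 15 leaves per level, two ROI spectra per leaf
  (120 rows), mean ROI spectrum = leaf endmember + 5·y·residue endmember
  (`responseCoef = 5` puts the residue abundance at 0.3 at the top
  level — a visible but minority contribution), 1% spectral noise, and a
  leaf-level multiplicative scatter (SD 2%) shared by both ROIs of a
  leaf so that group-aware splitting actually matters. The leaf effect is
  switched off for oracle tests whose expected values assume independent
  rows.

What the generator does **not** emulate: radiative-transfer leaf optics,
droplet drying physics, spatially structured (non-white) sensor noise,
wavelength-dependent noise, and any nonlinearity of the
concentration-to-spectrum response. The last point matters when reading
test outcomes: on an exactly linear synthetic response a well-tuned
linear model (PLSR) is already optimal, so GPR's advantage on real leaves
— which motivates the integrated pipeline — cannot be demonstrated on
these scenes, only GPR's correctness and stability can.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale problems
chosen to exercise every code path at comfortable interactive speed:
64 x 64 x 274 scenes for unmixing quality (ten seeds), the full
120-spectrum series for quantification (ten seeds), and smaller cubes
for structural properties. All generators and fitting routines take
explicit integer seeds; pipeline runs derive every internal seed from one
root seed and embed the seed and a configuration hash in each report, so
reruns are byte-identical.

# Known limitations

* Bilinear unmixing without pure pixels/bands is only identified up to
  rotation within the non-negativity cone; fit quality (LOF, $R^2$) is
  stable but individual abundance maps and proportions can drift between
  equally good solutions. Reference-spectrum initialization pins the
  solution in practice.
* Exact component proportions depend on the unit-maximum spectrum
  normalization convention (see above).
* The Mann-Whitney p-values ignore spatial autocorrelation.
* The LOD is reported in concentration percent only.
* GPR hyperparameter optimization is non-convex; different restart seeds
  can select different kernels when families fit equally well. The
  inner-CV selection makes the *predictions* stable even when the chosen
  family label varies.
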