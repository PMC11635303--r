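---
title: "Estimating potato LAI from hyperspectral canopy imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating potato LAI from hyperspectral canopy imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopylai` implements a complete analysis pipeline for estimating leaf area
index (LAI) of potato from very-high-resolution hyperspectral canopy imagery:
a treatment-structured trial simulator, three spectral feature families plus
gray-level texture features, successive-projections feature selection, and
three regression methods evaluated on a replicate-based split, down to
per-pixel LAI maps. This vignette records the model, the tunable parameters
and their defaults, and the design decisions taken where the procedure was
genuinely open.

## The estimation problem

LAI — one-sided leaf area per unit ground area — drives transpiration,
photosynthesis and yield formation, but direct measurement is destructive. At
very low flight altitude a hyperspectral imager sees both the canopy's
reflectance spectrum (pigment absorption, red-edge, NIR scattering) and its
spatial structure (row pattern, gap texture). The pipeline asks three
questions: how well do (i) raw band reflectance (OSR), first-order
differential spectra (FDSR) and vegetation indices (VIs), and (ii) Haralick
textures of the first principal-component (PC1) image predict LAI across
three tuber-development stages (BBCH 41/44/47); and (iii) whether combining
spectral and textural features improves the estimate.

## The simulated world

No imagery is distributed with the analysis, so the package generates a
synthetic trial whose structure matches the field design: two early-maturing
varieties crossed with a planting-density series (60/72/84 thousand
tubers/ha), a nitrogen series (0/112.5/225/337.5 kg/ha) and a potash series
(0/495/990 kg/ha K~2~O), sharing the standard-fertility control — 16
treatments, three replicate blocks, 48 plots of 32.5 m², observed at three
growth stages (144 samples).

**Ground truth.** Plot LAI is a multiplicative treatment response (rising
with density; rising with N up to the third rate, dipping at the luxury
rate; weak potash and variety effects), scaled so the design mean equals the
calibrated stage means 1.50 / 1.32 / 1.28, times lognormal plot noise
(log-sd 0.35), truncated to the observed range [0.29, 3.75]. Disc weights
are back-computed so the disc-weighing formula

$$\mathrm{LAI} = \frac{W_1 + W_2}{3\,W_1}\, S\, M$$

reproduces the stored LAI exactly ($W_1$: wet weight of the 60 punched
discs; $W_2$: wet weight of the remaining leaves of the 3 sampled plants;
$S$: total one-sided disc area; $M$: plants per m²). Two readings of $S$ are
possible; we take it as the **total** area of all 60 discs
($60 \pi r^2 \approx 3.016 \times 10^{-3}$ m² for a 0.8 cm punch), which is
the reading that yields LAI magnitudes in the observed range. $M$ is the
density level divided by 10⁴.

**Imagery.** Each pixel is a vegetation/soil linear mixture
$R(\lambda) = f R_{leaf}(\lambda) + (1-f) R_{soil}(\lambda)$ where the
plot-mean cover follows a Beer–Lambert law $f = 1 - e^{-k_{ext}\mathrm{LAI}}$
($k_{ext} = 0.5$, lognormal plot jitter log-sd 0.10: canopy architecture
varies, so reflectance is an informative but imperfect LAI proxy). Within
each plot, cover varies as planting-row stripes (4-pixel pitch, amplitude
$0.25 f(1-f)$, vanishing on bare soil and at closure) plus a correlated
Gaussian field whose amplitude $0.12/(1+\mathrm{LAI})$ (lognormal jitter
log-sd 0.08) *decreases* toward canopy closure — the causal channel that
gives image texture predictive value — plus a small LAI-independent
micro-texture field (amplitude 0.05) standing in for leaf-scale structure
that the real 1.4 cm imagery resolves but a 0.25 m simulation cannot. Two
nuisance fields supply the realism that keeps the feature families honestly
distinct: a smooth multiplicative illumination/BRDF gain (log-sd 0.08,
3 px correlation) that ratio indices cancel but raw bands and textures do
not, and a long-range soil-moisture brightness field on the soil endmember
(log-sd 0.12, 12 px). Soil brightens across acquisition dates
(0.90/1.00/1.10) and the leaf spectrum senesces mildly by starch
accumulation. Sensor noise is additive Gaussian (σ = 0.01 reflectance);
values are clipped to [0, 1.2]. The wavelength grid is 125 channels at
450 + 4k nm (450–946 nm): the sensor's printed "450–950 nm, 125 channels,
4 nm" is inconsistent by one channel, and we honor the channel count, with
the origin configurable.

These choices were calibrated once, against the qualitative structure the
pipeline is specified to exhibit (sensitivity ordering VIs > raw bands >
textures; PC1 carrying ≥ 90% of spectral variance on the default cube;
spectral families outranking textures in validation accuracy; combined
features not losing to VIs), and then frozen. What a green test establishes
is that the pipeline recovers the relationships the generator planted; it
says nothing about accuracy on real potato fields, and the paper-reported
field accuracies are deliberately not acceptance targets.

## Feature extraction

**Spectral (per plot).** The unweighted mean spectrum over mask-valid pixels
whose centers fall in the plot polygon gives 125 OSR columns. The
first-order differential is implemented exactly as used in the source
analysis, $\mathrm{FDSR}(i) = (R(i-1) - R(i+1))/\Delta\lambda$ — note this
equals $-2\times$ the conventional central difference; a
`fdsr_convention = "central"` flag provides the textbook form, but the
default reproduces the published transform verbatim, and endpoints replicate
the nearest interior value. The 30 vegetation indices are implemented
exactly as published (including SPVI's absolute value, RVSI's bracket
structure, and MTVI2's $R_{500}$ term); nominal wavelengths resolve to the
nearest grid channel with ties toward the lower wavelength.

**Textural (per plot).** Covariance PCA (band-centered, no variance scaling)
of the per-pixel spectra yields the PC1 score image; its sign is fixed by
the largest-magnitude loading element. The image is quantized to G = 32
levels by a linear stretch between the 2nd and 98th percentiles of valid
pixels. On every 5×5 window fully inside the valid mask (no padding), the
gray-level co-occurrence matrix is accumulated at offset (−1, +1) — the 45°
direction at distance 1 — symmetrized and normalized, and 8 simple + 10
advanced Haralick features are computed (natural logs, 0·log 0 := 0;
Haralick correlation in the Orfeo Toolbox convention
$(\sum ij\,p - \mu_t^2)/\sigma_t^2$ with row-marginal statistics, since
the published extraction used that toolbox). Run-length matrices trace
maximal equal-level runs along the window's 45° diagonals and yield the 10
higher-order features in Galloway's conventions, with gray levels shifted
by +1 so level 0 is weightable. Per plot, each of the 28 feature maps is
averaged over in-polygon pixels. Degenerate windows (zero marginal variance)
report correlations of 0 with a degeneracy flag rather than NaN.

The combined table is 144 × 308 (125 + 125 + 30 + 28), each column tagged
with its family.

## Feature selection

The successive projections algorithm selects minimally collinear subsets:
from a start column, it repeatedly projects all unselected (standardized)
columns onto the orthogonal complement of the selected span and appends the
largest-residual column. Because the original algorithm's random starts are
its only stochastic element, we run the chain from **every** candidate start.
For each chain prefix of length 1..kmax a multiple linear regression is
cross-validated (classic SPA-MLR; 5-fold, fold assignment seeded, RMSECV
averaged over 3 repeated assignments for stability) and the (start, k)
minimizing RMSECV wins, first minimum on ties. Defaults:
kmax = min(30, n/3). Selection runs on the calibration replicates only —
the leakage-free choice; `spa_on = "all"` reproduces the
selection-before-modeling protocol common in this literature. A
zero-variance column is excluded; a duplicated column can enter a chain at
most once.

The Pearson correlation screen (two-sided t test, flags at 0.05/0.01, with
the family-wise mean |r| summary) reproduces the sensitivity ranking:
on the default world VIs are by far the most LAI-sensitive family.

## Regression and evaluation

Three regressors, all implemented in-package because no implementation is
available in the execution environment: PLSR via SIMPLS with the component
count chosen by internal 5-fold CV up to 10; random forest regression with
the published rule ntree = 500, mtry = ⌊p/3⌋, nodesize 5, seeded bootstrap;
and Gaussian process regression with an ARD squared-exponential kernel plus
additive noise, inputs standardized, output centered, hyperparameters by
L-BFGS-B maximization of the log marginal likelihood with analytic gradients
from two deterministic starts. Per-dimension length-scales are the standard
choice for canopy-trait GPR and let the posterior down-weight uninformative
members of a mixed selected set.

Replicates 2–3 of every stage calibrate (96 samples), replicate 1 validates
(48). The printed accuracy equations of the source analysis are
typographically garbled, so the metrics use their standard forms:
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$,
$\mathrm{RMSE} = \sqrt{\mathrm{mean\ squared\ error}}$, and
$\mathrm{NRMSE} = 100\,\mathrm{RMSE}/\bar{y}$. The experiment grid covers
5 feature sets × 3 methods × 2 splits, plus a per-stage validation breakdown
of the best model.

**LAI maps.** The published mapping procedure is unstated; we apply the
plot-level-trained model pixel-wise (spectral features from the pixel
spectrum, textures from the window centered on the pixel), masked outside
plot polygons. Single pixels can sit far outside the plot-mean feature
domain, so the map writer offers an optional physical clip (the analysis
driver uses [0, 5]); linear models especially extrapolate badly on bare-soil
pixels.

## Numerical choices and degenerate inputs

* Quantization of a constant image maps to level 0 everywhere (valid, not an
  error); a plot with no computable texture window, a plot with zero valid
  pixels, and a cube with zero spectral variance are errors.
* A vegetation index that evaluates non-finite (division by zero) raises an
  error rather than propagating NaN.
* GPR adds 1e-8 to the kernel diagonal; noise variance is bounded below at
  1e-3 (log scale bound) to keep the Cholesky stable.
* All random draws derive from one master seed through a deterministic
  32-bit mixing function (`derive_seed`), so layout, truth, cubes, folds and
  bootstrap are individually re-derivable and the whole pipeline is
  bit-reproducible for a fixed configuration.

## Known limitations

* The generator is a mixture-plus-fields world, not radiative transfer: no
  BRDF or illumination geometry, no PROSAIL-style leaf biochemistry, no
  stitching artifacts. Absolute accuracies on this world (validation R²
  ≈ 0.88–0.95) are higher than published field results (≈ 0.45–0.70) because
  real canopies are harder; only the qualitative structure is comparable.
* The texture–roughness invariant (Spearman |ρ| ≥ 0.8 of Inertia and Entropy
  with the realized roughness amplitude) is asserted on the clean-signal
  scene (nuisance fields off). Under the full nuisance model the association
  weakens by design — that is precisely why textures rank last.
* The margin by which combined features beat VIs alone is small and varies
  across replicate worlds. The root cause is structural: SPA chains are
  response-blind and prefix-restricted, so the well-chosen VI subset is not
  reachable inside the 308-column candidate set, and the texture complement
  must be strong enough to compensate. The published single-field result is
  one draw from exactly this kind of variability.
* Texture features are computed at 0.25 m ground sampling; the real imagery
  is 1.4 cm. The micro-texture field emulates, but cannot reproduce,
  leaf-scale structure.
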