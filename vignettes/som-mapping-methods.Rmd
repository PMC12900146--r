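---
title: "Methods: wavelet fusion and SOM mapping with somfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet fusion and SOM mapping with somfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somfuse)
```

## The problem

Soil organic matter (SOM, g/kg) is the standard indicator of arable soil
quality, and mapping it over whole agricultural regions from a few hundred
field samples is a core task of digital soil mapping. A single bare-soil
satellite image is a noisy predictor: the reflectance observed on one date is
confounded by that date's moisture, residue and atmospheric state. `somfuse`
implements a pipeline that stabilizes the multispectral signal by fusing
several acquisition dates per band with a local-energy-weighted discrete
wavelet transform (LEW-DWT), augments it with phenology features extracted
from a decade of 16-day NDVI composites, and regresses SOM on the combined
covariate stack with a random forest and a shallow convolutional network
under 10-fold cross-validation.

## LEW-DWT fusion

Each spectral band is fused **across acquisition dates**: the inputs are the
same band observed on N dates, co-registered on one 30 m grid, and the
output is one fused band, so a seven-date, seven-band archive always yields
seven fused predictors.

Per band the chain is:

1. **Normalization.** Each date's band is min-max scaled to [0, 1] over its
   unmasked cells. Normalizing per image (rather than per stack) removes
   date-specific illumination offsets before energies are compared; the
   fused product stays in normalized space, where the downstream models
   standardize it anyway (an option rescales it to the baseline date's range
   for visualization).
2. **Energy weighting.** The global energy of a normalized image is
   E = sum(x_i^2), and the weight of date i is W_i = E_i / sum_j E_j.
   Energies are computed on the normalized bands before decomposition, and
   one weight per source image is used at every level rather than
   recomputing weights per level; with a single decomposition per source
   there is one coefficient set per source, so per-level weights would be
   redundant.
3. **Decomposition.** Two cascaded levels of the orthonormal 2-D Haar
   transform split each image into an approximation plane (LL) and
   horizontal/vertical/diagonal detail planes (HL/LH/HH) per level.
   One level retains too little spatial detail and three or more amplify
   high-frequency noise; two levels is the default (`fusion_config(levels =)`
   accepts 1-4). Odd-sized planes are padded by edge reflection and the
   padding is recorded, so reconstruction is exact to machine precision.
4. **Coefficient fusion.** The deepest LL plane is the energy-weighted mean
   of the sources, C_fused = sum_i W_i C_i - the approximation containing
   the most information dominates without discarding the rest. Every detail
   plane instead takes, per position, the coefficient of the source with the
   largest local energy (sum of squared coefficients over a centred 3 x 3
   window with reflective padding), so the sharpest observed edge or texture
   wins. Ties go to the baseline (sampling-year) date, then to the lowest
   date index. Both rules are configurable (`rule_low`, `rule_high`); the
   mean rule for all planes reproduces the traditional-DWT control, and
   skipping fusion entirely ("simple splicing") keeps every date-band as its
   own feature. For detail planes smaller than the window (a 2-level
   transform of a small tile) the window shrinks to the largest odd size
   that fits, degrading gracefully to per-cell energy.
5. **Reconstruction.** The fused pyramid is inverted and cropped to the
   input shape. A cell masked on any input date is masked in the fused band.

Fusion quality is quantified against the baseline date with the three
conventional metrics: mean spectral angle (SAM, radians), Shannon entropy of
a 256-level quantization (IE, bits) and the forward-difference average
gradient (AG). The source publication tabulates these without formulas, so
the standard definitions from the fusion-quality literature are used.

## NDVI phenology features

Per pixel, ten years of 16-day NDVI composites (23 per year) are smoothed
with a Savitzky-Golay filter and summarized into six features: the smoothed
minimum, maximum and population standard deviation (`n_min`, `n_max`,
`n_std`), the growing-season length (`n_gsl`), and the amplitude and phase
of the first annual harmonic (`n_amplitude`, `n_phase`), plus the long-term
mean and standard deviation of the raw series (`mndvi`, `sdndvi`).

Choices the source conditions left open, fixed here once:

* **S-G window 7, order 3** (configurable): the common setting for 16-day
  composites - wide enough to suppress single-composite dropouts, local
  enough to preserve the double peak of a wheat-maize rotation. The filter
  is applied to the concatenated multi-year series, not per year, so year
  boundaries are smoothed consistently; ends are handled by the polynomial
  fit of the edge window (`signal::sgolayfilt`'s edge rows).
* **Season threshold**: dynamic, `n_min + 0.2 * (n_max - n_min)`, the usual
  20%-of-amplitude phenology rule; a fixed NDVI value can be supplied. The
  season length is the mean count of composites at or above the threshold
  per whole year (x16 for days). A zero-amplitude series is defined to have
  a full-year season.
* **Phase convention**: the harmonic at the annual frequency of the full
  Y-year series is extracted from the DFT; amplitude `2|X_Y|/N` and phase
  `atan2(-Im X_Y, Re X_Y)`, fixed by the contract that
  `A*cos(2*pi*t/23 - phi)` returns exactly `(A, phi)` (radians, (-pi, pi]).
  `n_std` is the population standard deviation.

Because the filter is linear, the per-pixel map materializes it once as an
n x n operator and applies it to all pixels as a single matrix product.

## Covariates, combinations and selection

Environmental covariates arrive at heterogeneous resolutions and are
resampled to the analysis grid with cubic convolution (continuous) or
nearest neighbour (categorical); categorical covariates are one-hot encoded
to avoid fake ordinality. Multi-temporal products are enumerated as the
baseline-anchored subsets of the date set - choosing m dates means the
baseline plus m-1 of the remaining n, C(n, m-1) subsets - so a seven-date
archive yields 1, 6, 15, 20, 15, 6, 1 products for m = 1..7 (64 in all).

Recursive feature elimination ranks the environmental block: an RF ranker
(250 trees, depth 6) scores the current set, the weakest feature is removed,
and the loop repeats until 24 remain; ten repeats vote, and features are
ranked by selection frequency with ties broken by mean elimination order.
Selection runs on the environmental block only, with the NDVI and
multi-temporal blocks appended afterwards (the alternative order is a
configuration choice). One honest limitation: ensemble impurity importance
does not split credit between exactly collinear features - different trees
use different copies interchangeably - so recursive elimination with an RF
ranker cannot be relied on to discard exact duplicates in favour of unique
features; redundant copies can co-survive. The test suite asserts the
behaviours that are robust (a genuine driver is selected in every repeat;
the procedure is deterministic under its seed).

## Models and evaluation

**Random forest**: 250 trees of depth 6, chosen from grids of 100-350 trees
and depths 3-8 by an optional inner grid search; impurity importances,
normalized to percentages, are aggregated into category shares that both
sum to 100.

**Shallow CNN**: each sample is a 7 x 7 patch of the covariate stack centred
on the sample pixel (edge patches are reflection-filled; the centre always
equals the point value). The architecture is conv 3x3 x32 -> maxpool 2x2 ->
conv 2x2 x48 -> dropout 0.2 -> conv 2x2 x24 -> conv 2x2 x12 -> dropout 0.2
-> flatten -> dense 80 -> dropout 0.1 -> dense 15 -> dense 1, all ReLU with
a linear output, trained with Adam on mean squared error. With valid
convolutions this layer list is dimensionally infeasible on a 7 x 7 input
(7 -> 5 -> pool -> 2 -> 1 leaves nothing for two further 2 x 2
convolutions), so the 2 x 2 convolutions retain their 2 x 2 extent via
bottom/right zero padding; the flatten then sees 2 x 2 x 12 = 48 units.
Training details the source left open: learning rate 1e-3, batch 16, at
most 300 epochs with early stopping (patience 30) on a 10% held-out split
of each training fold; the target is z-scored internally and predictions
mapped back to g/kg; dropout is active only during training, so inference
is deterministic. The network and its backpropagation are implemented
directly with matrix operations, and the gradients are verified against
finite differences in the test suite.

**Evaluation**: seeded 10-fold cross-validation; feature (and patch
channel) standardization is fitted on each training fold only. MAE,
RMSE and R^2 = 1 - SS_res/SS_tot are computed per fold and pooled over the
concatenated out-of-fold predictions; SS_tot is taken about the observed
mean, R^2 is not clamped and is reported as missing for a zero-variance
target. Derived reporting statistics (relative changes, percent reductions,
RMSE/MAE ratios, relative RMSE, coefficient of variation) are rounded to
one decimal, ratios to two.

**Maps**: per-pixel predictions are the mean across the ten fold models and
the uncertainty map is their standard deviation - consistent with the
cross-validation design and zero when the folds agree. (Across-tree spread
or MC-dropout would be alternatives; the fold-spread definition is the one
implemented and labelled in the outputs.) A pixel masked in any input
channel is masked in both maps.

## The synthetic study area

No public deposit of the original field samples or imagery exists, so the
package ships a generator whose defaults emulate the documented study
conditions, with known ground truth at every stage:

* **SOM field**: a Gaussian random field (white noise smoothed by circular
  convolution with a Gaussian kernel, correlation length 10 pixels on a
  200 x 200, 30 m grid) rescaled to exactly mean 20.12 and SD 2.42 g/kg -
  the field-survey statistics (CV 12%).
* **Reflectance**: seven bands (coastal-aerosol through SWIR2) on seven
  dates; each band is an affine map of SOM with negative loadings strongest
  in NIR/SWIR (the documented inverse reflectance-SOM relationship), plus a
  smooth date-specific illumination residual (SD 0.02) and per-pixel noise
  (SD 0.005). Illumination residuals are spatially smooth because the
  date-to-date confounders they emulate (atmospheric state, moisture) vary
  at scales much larger than a pixel.
* **NDVI**: 10 years x 23 composites; each year carries two Gaussian pulses
  (centres 8.5 and 16.5 composites, amplitudes 0.45/0.40) over a 0.25
  baseline - the winter-wheat and summer-maize peaks - scaled by a
  SOM-linked productivity factor (8% per SOM standard deviation) plus noise
  (SD 0.04). The resulting pixel-level maxima (~0.7-0.8) and minima
  (~0.2-0.3) match the documented smoothed-series ranges.
* **Covariates**: the documented suite of climate, parent-material,
  topographic, thermal, soil and anthropogenic variables, each a mixture of
  the standardized SOM field and an independent random field. The
  independent field is residualized against the SOM field first, so the
  configured correlation is realized exactly over the scene. Soil-moisture
  variables are strongest (rho 0.4-0.6), climate moderate, topography weak
  (an alluvial plain); lithology is categorical (quantile classes of an
  independent field).
* **Samples**: 500 points drawn uniformly without replacement (a
  quantile-stratified mode is available), read at pixel centres with
  measurement noise of SD 0.25 x 2.42 g/kg - noise at 25% of the signal SD.

What the generator does **not** emulate: radiative transfer, clouds and
gaps, geolocation error, spatially correlated measurement error, and the
nonlinear, interaction-rich soil-landscape relationships of real terrain.
Passing recovery tests on these scenes certifies the pipeline's mechanics
(fusion fidelity, feature extraction, fold hygiene, model plumbing), not
field-scale accuracy; absolute synthetic accuracies are higher than any
real campaign would produce.

## Problem sizes and numerical choices

The standard benchmark (`som_benchmark()`, also run by
`scripts/acceptance.R`) uses the default 200 x 200 scene with 500 samples
and 10-fold cross-validation; the CNN trains with a cap of 80 epochs
(patience 15), which its early-stopping curve reaches comfortably on these
scenes. Unit tests run the same code on 24 x 24 scenes with 60 samples.
Wavelet reconstruction is asserted to 1e-8 relative error, harmonic
recovery to 1e-6, standardization round-trips to 1e-10; energy weights with
an all-zero energy vector, fully masked images, zero-variance features
(centred, flagged) and zero-variance targets (R^2 missing) are explicit
error or degenerate-path cases. All internal arithmetic is double
precision; GeoTIFFs are written float32.

## Known limitations

* Reprojection between CRSs is out of scope; inputs must share a CRS.
* The GeoTIFF reader targets uncompressed, strip-organized files (what the
  toolkit writes and plain GIS exports produce); tiled or compressed files
  are rejected with a clear error.
* The RF-ranked recursive elimination cannot discard exact duplicates (see
  above).
* The shallow CNN is tuned for 7 x 7 patches; other window sizes require a
  different dense-head geometry.
* Season-length and harmonic features assume whole 23-composite years;
  trailing partial years are trimmed.
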