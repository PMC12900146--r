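# somfuse

Digital soil mapping of soil organic matter (SOM, g/kg) from multi-temporal
multispectral imagery, for soil scientists and remote-sensing analysts who
need regional SOM maps from a few hundred field samples plus free satellite
archives.

A single bare-soil acquisition is a noisy SOM predictor: its reflectance is
confounded by that date's moisture, residue and atmosphere. `somfuse`
stabilizes the spectral signal by fusing several acquisition dates of each
band with a **local-energy-weighted discrete wavelet transform (LEW-DWT)**:
every date's band is min-max normalized, decomposed by a 2-level orthonormal
Haar transform, and recombined so that the deepest approximation plane is the
energy-weighted mean of the dates,

    E_i = Σ x²,   W_i = E_i / Σ_j E_j,   C_fused = Σ_i W_i · C_i,

while each detail coefficient is taken from the date with the largest local
energy in a 3 × 3 window (ties to the baseline sampling-year date). The fused
bands join two further covariate blocks:

* **Tn** — per-pixel phenology from a decade of 16-day NDVI composites
  (NDVI = (NIR − RED)/(NIR + RED)): Savitzky–Golay-smoothed minimum, maximum
  and SD, threshold-based growing-season length, and the amplitude and phase
  of the first annual harmonic;
* **Ev** — environmental covariates (climate, parent material, topography,
  land-surface temperature, soil, anthropogenic) resampled to the common
  grid (cubic convolution / nearest neighbour) and screened by repeated
  recursive feature elimination under a random-forest ranker.

SOM is then regressed on the stack with a random forest (250 trees, depth 6)
and a shallow 3-convolution CNN over 7 × 7 neighbourhood patches, evaluated
by pooled 10-fold cross-validation (MAE, RMSE, R²), with per-pixel
prediction and fold-spread uncertainty maps. Fusion fidelity is scored by
spectral angle, information entropy and average gradient. A seeded
synthetic-scene generator reproduces the documented study conditions (SOM
mean 20.12, SD 2.42 g/kg; wheat–maize double-peak NDVI; negative SOM–
reflectance loadings strongest in NIR/SWIR) so every stage is testable with
known ground truth.

## Worked example

Fuse the SWIR1 band across seven synthetic acquisition dates, then
cross-validate a random forest on the environmental covariates:

```r
library(somfuse)

recipe <- scene_recipe(nrow = 60, ncol = 60, n_samples = 150, seed = 42)
som    <- make_som_field(recipe)        # ground-truth SOM field (g/kg)
parts  <- make_scene(recipe, som)

swir1  <- lapply(parts$scene, function(d) d$SWIR1)
fused  <- lew_dwt_fuse(swir1, fusion_config(baseline_index = 6))
cor(as.vector(fused$values), as.vector(som$values))
#> [1] -0.709        # single dates average r = -0.477: fusion sharpens signal

samples <- draw_samples(recipe, som)
tab <- assemble_feature_table(samples, parts$covariates,
                              kinds = parts$covariate_kinds,
                              categorical = parts$categorical)
ev <- cross_validate(rf_spec(), tab, folds = 10, seed = 42)
ev
#> EvalReport: pooled MAE 0.699, RMSE 0.880, R2 0.873 (10 folds, seed 42)
```

The fused band correlates more strongly with the SOM field than any single
date because date-specific illumination residuals average out of the
approximation plane while the sharpest detail coefficients are retained.
The pooled out-of-fold R² of 0.873 says the covariate suite explains ~87% of
the sample SOM variance on this (deliberately friendly) synthetic scene.

Variable importance with category aggregation:

```r
fit <- train_rf(rf_spec(), tab[setdiff(names(tab), c("sample_id","x","y","som"))],
                tab$som, seed = 42)
variable_importance(fit, attr(tab, "feature_kinds"))$per_category[1:3, ]
#>               category importance_percent
#> 1                 soil           39.45380
#> 2              climate           25.84638
#> 3 land-surface-thermal           15.52188
```

Soil-moisture covariates dominate, as configured in the recipe — the
generator's way of emulating moisture-driven SOM spatial structure.

The full experiment (fusion → features → selection → both models → report
bundle with maps) is one call: `run_pipeline(list(seed = 1), out_dir = "out")`,
or from a shell, `inst/scripts/somfuse run --out out`.

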