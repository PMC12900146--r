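# Seeded synthetic study areas with known ground truth.
#
# The generator emulates the inputs of a cropland SOM mapping campaign on a
# Yellow-River-alluvium-like plain: a spatially autocorrelated SOM field
# with the field-survey statistics (mean 20.12, SD 2.42 g/kg), seven-band
# reflectance for several acquisition dates in which reflectance decreases
# with SOM (strongest in NIR/SWIR) plus smooth date-specific illumination
# residuals, a 16-day NDVI series with the double-peak winter-wheat /
# summer-maize cycle whose productivity scales with SOM, and a suite of
# environmental covariates with configured correlations to SOM.

LANDSAT_BANDS <- c("Coastal", "Blue", "Green", "Red", "NIR", "SWIR1", "SWIR2")

default_band_params <- function() {
  data.frame(
    band = LANDSAT_BANDS,
    intercept = c(0.10, 0.11, 0.14, 0.17, 0.30, 0.34, 0.28),
    # reflectance change per g/kg SOM: negative, strongest in NIR/SWIR
    loading = -c(0.0008, 0.0010, 0.0015, 0.0020, 0.0045, 0.0050, 0.0040))
}

# Environmental covariate suite: name, category and target correlation with
# the SOM field. Soil-moisture variables dominate, climate is moderate and
# topography weak (an alluvial plain has little relief signal). RL is
# categorical (lithology classes).
default_covariates <- function() {
  df <- rbind(
    data.frame(name = c("MAAT", "MDR", "MAR", "ATS", "MAWM", "MACM", "MASR",
                        "WS", "WVP", "MAP", "PSD"),
               kind = "climate",
               rho = c(-0.35, -0.15, -0.12, -0.20, -0.18, 0.15, -0.10,
                       -0.08, 0.25, 0.45, 0.30)),
    data.frame(name = c("RT", "RL"), kind = "parent material",
               rho = c(0.15, 0)),
    data.frame(name = c("DEM", "SG", "SA", "PLC", "PRC", "TWI", "TPI"),
               kind = "topographic",
               rho = c(-0.12, -0.08, 0.02, 0.05, -0.05, 0.15, -0.06)),
    data.frame(name = c("HDLST", "MDLST", "SDDLST", "HNLST", "MNLST",
                        "SDNLST", "MLSTS3", "MLSTS6", "MLSTA", "MLSTW"),
               kind = "land-surface-thermal",
               rho = c(-0.25, -0.28, 0.10, -0.20, -0.22, 0.08, -0.18,
                       -0.24, -0.20, -0.15)),
    data.frame(name = c("GWTD", "MSM", "SDSM", "HSM", "LSM", "MSMS3",
                        "MSMS6", "MSMA", "MSMW"),
               kind = "soil",
               rho = c(-0.30, 0.60, 0.18, 0.45, 0.40, 0.52, 0.55, 0.48,
                       0.42)),
    data.frame(name = c("PD", "BUV", "RD", "HAHF"), kind = "anthropogenic",
               rho = c(-0.10, -0.12, -0.08, -0.05)))
  rownames(df) <- NULL
  df
}

#' Recipe for a synthetic study area
#'
#' Collects every generative parameter of the synthetic scene. The defaults
#' reproduce the study conditions the toolkit is benchmarked under: a
#' 200 x 200 pixel, 30 m grid; SOM mean 20.12 and SD 2.42 g/kg; seven
#' acquisition dates of seven bands with SOM-dependent reflectance; ten
#' years of 23 NDVI composites with a wheat-maize double peak; and the
#' default covariate suite.
#'
#' @param nrow,ncol Grid size in pixels.
#' @param pixel_size Pixel edge in metres (default 30).
#' @param origin Map coordinates of the upper-left corner.
#' @param crs CRS identifier.
#' @param correlation_length SOM Gaussian-random-field correlation scale in
#'   pixels (0 = white noise).
#' @param som_mean,som_sd Target SOM mean and SD (g/kg).
#' @param dates Acquisition-date labels; `baseline_date` must be among
#'   them.
#' @param baseline_date The sampling-year reference date.
#' @param band_params Data frame `band`, `intercept`, `loading`
#'   (reflectance per g/kg).
#' @param illumination_sd SD of the smooth per-date illumination field
#'   (reflectance units).
#' @param band_noise_sd Per-pixel reflectance noise SD.
#' @param years,samples_per_year NDVI series length (default 10 x 23).
#' @param ndvi_base Off-season NDVI level.
#' @param ndvi_peaks Data frame `center`, `width`, `amplitude` of the
#'   within-year Gaussian pulses (composite units).
#' @param ndvi_som_gain Productivity gain per SOM standard deviation.
#' @param ndvi_noise_sd NDVI observation noise SD.
#' @param covariates Data frame `name`, `kind`, `rho` of covariate targets.
#' @param covariate_correlation_length Correlation scale of covariate
#'   fields (pixels).
#' @param n_samples Number of soil sample points.
#' @param sample_noise_sd SOM measurement noise SD (g/kg); the default is
#'   25% of `som_sd`.
#' @param seed Integer seed fixing every draw.
#' @return An object of class `SceneRecipe`.
#' @export
scene_recipe <- function(nrow = 200L, ncol = 200L, pixel_size = 30,
                         origin = c(500000, 4070000), crs = "EPSG:32650",
                         correlation_length = 10,
                         som_mean = 20.12, som_sd = 2.42,
                         dates = c("2014", "2015", "2017", "2018", "2019",
                                   "2020", "2023"),
                         baseline_date = "2020",
                         band_params = default_band_params(),
                         illumination_sd = 0.02, band_noise_sd = 0.005,
                         years = 10L, samples_per_year = 23L,
                         ndvi_base = 0.25,
                         ndvi_peaks = data.frame(
                           center = c(8.5, 16.5), width = c(1.8, 2.0),
                           amplitude = c(0.45, 0.40)),
                         ndvi_som_gain = 0.08, ndvi_noise_sd = 0.04,
                         covariates = default_covariates(),
                         covariate_correlation_length = 12,
                         n_samples = 500L, sample_noise_sd = 0.25 * 2.42,
                         seed = 1L) {
  stopifnot(som_sd > 0, band_noise_sd >= 0, ndvi_noise_sd >= 0,
            sample_noise_sd >= 0, baseline_date %in% dates)
  structure(as.list(environment()), class = "SceneRecipe")
}

#' Spatially autocorrelated standard Gaussian field
#'
#' White noise smoothed by circular convolution with a Gaussian kernel of
#' scale `correlation_length` (in pixels), then re-standardized to zero mean
#' and unit variance. Zero correlation length returns the white field.
#' Draws from the current RNG stream.
#'
#' @param nrow,ncol Field size.
#' @param correlation_length Gaussian kernel scale in pixels.
#' @return Numeric matrix with mean 0 and SD 1 (population).
#' @export
gaussian_random_field <- function(nrow, ncol, correlation_length = 0) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (correlation_length > 0) {
    di <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
    dj <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
    kern <- exp(-outer(di^2, dj^2, "+") / (2 * correlation_length^2))
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      length(z)
  }
  (z - mean(z)) / sqrt(mean((z - mean(z))^2))
}

recipe_transform <- function(recipe) {
  c(recipe$origin[1], recipe$origin[2], recipe$pixel_size, recipe$pixel_size)
}

#' Generate the ground-truth SOM field
#'
#' A spatially autocorrelated Gaussian random field rescaled to exactly the
#' recipe's SOM mean and (population) SD, reproducible under the recipe
#' seed.
#'
#' @param recipe A [scene_recipe()].
#' @return A `RasterGrid` in g/kg.
#' @export
make_som_field <- function(recipe) {
  z <- with_seed(recipe$seed,
                 gaussian_random_field(recipe$nrow, recipe$ncol,
                                       recipe$correlation_length))
  raster_grid(recipe$som_mean + recipe$som_sd * z,
              recipe_transform(recipe), recipe$crs)
}

ndvi_annual_cycle <- function(recipe) {
  t_in_year <- (seq_len(recipe$samples_per_year) - 0.5)
  pulse <- rep(0, recipe$samples_per_year)
  for (p in seq_len(nrow(recipe$ndvi_peaks))) {
    pk <- recipe$ndvi_peaks[p, ]
    pulse <- pulse + pk$amplitude *
      exp(-(t_in_year - pk$center)^2 / (2 * pk$width^2))
  }
  pulse
}

#' Generate the full synthetic scene from a SOM field
#'
#' Produces (1) a multi-date, multi-band reflectance stack in which each
#' band is an affine map of SOM plus a smooth date-specific illumination
#' residual and pixel noise, (2) a 16-day NDVI stack whose double-peak
#' annual cycle is scaled by a SOM-linked productivity factor, and (3) the
#' covariate rasters, each a mixture of the standardized SOM field and an
#' independent random field realizing the configured correlation. Fully
#' reproducible under the recipe seed.
#'
#' @param recipe A [scene_recipe()].
#' @param som The SOM `RasterGrid` from [make_som_field()].
#' @return A list with `scene` (list date -> list band -> `RasterGrid`),
#'   `ndvi_stack` (list of `RasterGrid`s in time order), `covariates`
#'   (named list of `RasterGrid`s), `covariate_kinds` (named character
#'   vector) and `categorical` (covariate names to one-hot encode).
#' @export
make_scene <- function(recipe, som) {
  stopifnot(inherits(som, "RasterGrid"),
            nrow(som$values) == recipe$nrow, ncol(som$values) == recipe$ncol)
  tf <- recipe_transform(recipe)
  nr <- recipe$nrow; nc <- recipe$ncol
  som_z <- (som$values - mean(som$values)) / stats::sd(som$values)
  grid_of <- function(v) raster_grid(v, tf, recipe$crs)

  scene <- with_seed(recipe$seed + 1L, {
    lapply(stats::setNames(recipe$dates, recipe$dates), function(d) {
      illum <- recipe$illumination_sd *
        gaussian_random_field(nr, nc, recipe$correlation_length) +
        stats::runif(1, -0.02, 0.02)
      bands <- lapply(seq_len(nrow(recipe$band_params)), function(b) {
        bp <- recipe$band_params[b, ]
        refl <- bp$intercept + bp$loading * som$values + illum +
          matrix(stats::rnorm(nr * nc, sd = recipe$band_noise_sd), nr, nc)
        grid_of(refl)
      })
      stats::setNames(bands, recipe$band_params$band)
    })
  })

  cycle <- ndvi_annual_cycle(recipe)
  n_t <- recipe$years * recipe$samples_per_year
  prod_factor <- 1 + recipe$ndvi_som_gain * som_z
  ndvi_stack <- with_seed(recipe$seed + 2L, {
    lapply(seq_len(n_t), function(t) {
      within <- ((t - 1L) %% recipe$samples_per_year) + 1L
      v <- recipe$ndvi_base + prod_factor * cycle[within] +
        matrix(stats::rnorm(nr * nc, sd = recipe$ndvi_noise_sd), nr, nc)
      grid_of(pmin(pmax(v, -1), 1))
    })
  })

  cov_tab <- recipe$covariates
  som_zs <- (som_z - mean(som_z)) / sqrt(mean((som_z - mean(som_z))^2))
  covariates <- with_seed(recipe$seed + 3L, {
    out <- lapply(seq_len(nrow(cov_tab)), function(i) {
      rho <- cov_tab$rho[i]
      indep <- gaussian_random_field(nr, nc,
                                     recipe$covariate_correlation_length)
      # residualize against the SOM field so the configured correlation is
      # realized exactly over the scene, not merely in expectation
      resid <- indep - mean(indep * som_zs) * som_zs
      resid <- (resid - mean(resid)) / sqrt(mean((resid - mean(resid))^2))
      v <- rho * som_zs + sqrt(1 - rho^2) * resid
      if (cov_tab$name[i] == "RL") {
        # lithology classes: quantile bins of an independent field
        v <- matrix(as.numeric(cut(indep, stats::quantile(indep, 0:4 / 4),
                                   include.lowest = TRUE, labels = FALSE)),
                    nr, nc)
      }
      grid_of(v)
    })
    stats::setNames(out, cov_tab$name)
  })

  list(scene = scene, ndvi_stack = ndvi_stack, covariates = covariates,
       covariate_kinds = stats::setNames(cov_tab$kind, cov_tab$name),
       categorical = "RL")
}

#' Draw soil sample points from the SOM field
#'
#' Uniform-without-replacement pixel draw (or an optional quantile-stratified
#' mode), reading SOM at pixel centres with optional measurement noise.
#'
#' @param recipe A [scene_recipe()].
#' @param som The SOM `RasterGrid`.
#' @param n Number of samples (default `recipe$n_samples`).
#' @param stratified Stratify the draw over SOM quantile bins.
#' @param bins Number of strata when `stratified`.
#' @param noise_sd Measurement noise SD in g/kg (default
#'   `recipe$sample_noise_sd`).
#' @return Data frame `sample_id`, `x`, `y`, `som` (g/kg).
#' @export
draw_samples <- function(recipe, som, n = recipe$n_samples,
                         stratified = FALSE, bins = 5L,
                         noise_sd = recipe$sample_noise_sd) {
  npix <- length(som$values)
  if (n > npix) stop("more samples than pixels")
  idx <- with_seed(recipe$seed + 4L, {
    if (stratified) {
      qs <- stats::quantile(som$values, seq(0, 1, length.out = bins + 1))
      strata <- cut(som$values, unique(qs), include.lowest = TRUE,
                    labels = FALSE)
      per <- diff(round(seq(0, n, length.out = bins + 1)))
      unlist(lapply(seq_len(bins), function(b) {
        pool <- which(strata == b)
        sample(pool, min(per[b], length(pool)))
      }))
    } else sample.int(npix, n)
  })
  rc <- arrayInd(idx, dim(som$values))
  tf <- som$transform
  x <- tf[1] + (rc[, 2] - 0.5) * tf[3]
  y <- tf[2] - (rc[, 1] - 0.5) * tf[4]
  noise <- if (noise_sd > 0)
    with_seed(recipe$seed + 5L, stats::rnorm(length(idx), sd = noise_sd))
  else 0
  data.frame(sample_id = seq_along(idx), x = x, y = y,
             som = som$values[idx] + noise)
}
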