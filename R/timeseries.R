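# Per-pixel NDVI time-series smoothing and phenology features.
#
# Series follow a 16-day compositing cadence with 23 samples per year. The
# Savitzky-Golay smoother delegates to signal::sgolayfilt, whose edge rows
# fit the edge window's polynomial, matching the stated end-handling
# contract. Because the filter is linear, the per-pixel map applies it as a
# single n x n operator matrix built once per (length, window, order).

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - RED) / (NIR + RED), clipped to \[-1, 1\]. A zero denominator
#' yields `NA` (masked output).
#'
#' @param nir,red Near-infrared and red reflectances (vectors or matrices of
#'   equal shape).
#' @return NDVI values with the input shape.
#' @examples
#' ndvi(0.5, 0.1)  # 0.6667
#' @export
ndvi <- function(nir, red) {
  denom <- nir + red
  out <- (nir - red) / denom
  out[denom == 0] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' NDVI series container
#'
#' @param values Numeric NDVI values in \[-1, 1\].
#' @param samples_per_year Composites per year (default 23, the 16-day
#'   cadence).
#' @param mask Optional logical vector, `TRUE` marking unusable samples.
#' @return An object of class `NdviSeries`.
#' @export
ndvi_series <- function(values, samples_per_year = 23L, mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(length(mask) == length(values))
  values[mask] <- NA_real_
  structure(list(values = values, times = seq_along(values) - 1L,
                 samples_per_year = as.integer(samples_per_year),
                 mask = mask),
            class = "NdviSeries")
}

series_values <- function(x) if (inherits(x, "NdviSeries")) x$values else
  as.numeric(x)

# n x n linear operator equivalent to sgolayfilt on a length-n series
sg_operator <- local({
  cache <- new.env(parent = emptyenv())
  function(n, window, order) {
    key <- paste(n, window, order, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    eye <- diag(n)
    S <- apply(eye, 2, function(e) signal::sgolayfilt(e, p = order, n = window))
    cache[[key]] <- S
    S
  }
})

#' Savitzky-Golay smoothing of an NDVI series
#'
#' Replaces each sample by the centre value of a local least-squares
#' polynomial fit over a moving window; series ends are handled by the
#' polynomial fit of the edge window. Polynomials of degree at most `order`
#' pass through unchanged. Masked samples are linearly interpolated before
#' filtering and re-masked afterwards only if the whole series is unusable.
#'
#' @param series An `NdviSeries` or numeric vector.
#' @param window Odd window length (default 7), at most the series length.
#' @param order Polynomial order (default 3), less than `window`.
#' @return Smoothed series of the same type as the input.
#' @export
sg_filter <- function(series, window = 7L, order = 3L) {
  v <- series_values(series)
  n <- length(v)
  if (window %% 2L == 0L || order >= window || window > n)
    stop("need odd window, order < window, window <= series length")
  if (anyNA(v)) {
    ok <- which(!is.na(v))
    if (length(ok) < 2) stop("series has fewer than 2 usable samples")
    v <- stats::approx(ok, v[ok], xout = seq_len(n), rule = 2)$y
  }
  sm <- signal::sgolayfilt(v, p = order, n = window)
  if (inherits(series, "NdviSeries"))
    ndvi_series(sm, series$samples_per_year) else sm
}

#' Distribution features of a smoothed NDVI series
#'
#' @param smoothed An `NdviSeries` or numeric vector with at least two
#'   unmasked samples.
#' @return Named vector `c(n_min, n_max, n_std)`; `n_std` is the population
#'   standard deviation.
#' @export
stat_features <- function(smoothed) {
  v <- series_values(smoothed)
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 unmasked samples")
  c(n_min = min(v), n_max = max(v),
    n_std = sqrt(mean((v - mean(v))^2)))
}

#' Growing season length by thresholding
#'
#' Counts, per year, the composites whose smoothed NDVI is at or above a
#' threshold and averages the counts over whole years. The default dynamic
#' threshold is `n_min + 0.2 * (n_max - n_min)`; a fixed NDVI threshold can
#' be supplied instead. A zero-amplitude (constant) series is defined to
#' have a full-year growing season.
#'
#' @param smoothed An `NdviSeries` or numeric vector covering at least one
#'   full year.
#' @param threshold Fixed NDVI threshold, or `NULL` (default) for the
#'   dynamic 20%-of-amplitude rule.
#' @param samples_per_year Composites per year (default 23).
#' @return Mean number of composites per year at or above the threshold
#'   (multiply by 16 for days).
#' @export
growing_season_length <- function(smoothed, threshold = NULL,
                                  samples_per_year = 23L) {
  v <- series_values(smoothed)
  spy <- if (inherits(smoothed, "NdviSeries")) smoothed$samples_per_year else
    as.integer(samples_per_year)
  n_years <- length(v) %/% spy
  if (n_years < 1) stop("need at least one full year of samples")
  v <- v[seq_len(n_years * spy)]
  if (is.null(threshold)) {
    rng <- range(v, na.rm = TRUE)
    if (rng[2] == rng[1]) return(as.numeric(spy))
    threshold <- rng[1] + 0.2 * (rng[2] - rng[1])
  }
  above <- matrix(v >= threshold, nrow = spy)
  mean(colSums(above, na.rm = TRUE))
}

#' First-harmonic amplitude and phase of the annual NDVI cycle
#'
#' Discrete Fourier transform of the smoothed series trimmed to whole years;
#' the annual-frequency component (index = number of years) yields the
#' amplitude `2|X|/N` and phase `atan2(-Im X, Re X)`, so that a series
#' `A * cos(2*pi*t/23 - phi)` returns `(A, phi)`.
#'
#' @param smoothed An `NdviSeries` or numeric vector covering at least one
#'   full year.
#' @param samples_per_year Composites per year (default 23).
#' @return Named vector `c(n_amplitude, n_phase)`; phase in radians in
#'   `(-pi, pi]`.
#' @export
first_harmonic <- function(smoothed, samples_per_year = 23L) {
  v <- series_values(smoothed)
  spy <- if (inherits(smoothed, "NdviSeries")) smoothed$samples_per_year else
    as.integer(samples_per_year)
  n_years <- length(v) %/% spy
  if (n_years < 1) stop("need at least one full year of samples")
  v <- v[seq_len(n_years * spy)]
  X <- stats::fft(v)[n_years + 1L]
  c(n_amplitude = 2 * Mod(X) / length(v),
    n_phase = atan2(-Im(X), Re(X)))
}

#' Per-pixel phenology feature maps from an NDVI stack
#'
#' Applies Savitzky-Golay smoothing and the six time-series features to
#' every pixel of a co-registered NDVI stack, plus the long-term mean
#' (`mndvi`) and standard deviation (`sdndvi`) of the raw, unsmoothed
#' series. Pixels masked in any composite are masked in every feature map.
#'
#' @param stack List of co-registered `RasterGrid`s, one per composite date,
#'   in time order; length a multiple of `samples_per_year` for the
#'   harmonic/season features.
#' @param window,order Savitzky-Golay parameters.
#' @param samples_per_year Composites per year (default 23).
#' @param gsl_threshold Fixed growing-season threshold or `NULL` for the
#'   dynamic rule.
#' @return Named list of `RasterGrid`s: `n_min`, `n_max`, `n_std`, `n_gsl`,
#'   `n_amplitude`, `n_phase`, `mndvi`, `sdndvi`.
#' @export
per_pixel_features <- function(stack, window = 7L, order = 3L,
                               samples_per_year = 23L, gsl_threshold = NULL) {
  assert_coregistered(stack)
  ref <- stack[[1]]
  n_t <- length(stack)
  npix <- length(ref$values)
  X <- vapply(stack, function(g) as.vector(g$values), numeric(npix))
  bad <- !stats::complete.cases(X)
  Xw <- X
  if (any(bad)) Xw[bad, ] <- 0          # placeholder; re-masked at the end

  S <- sg_operator(n_t, window, order)
  Xs <- Xw %*% t(S)

  n_years <- n_t %/% samples_per_year
  if (n_years < 1) stop("stack shorter than one year")
  nT <- n_years * samples_per_year
  Xy <- Xs[, seq_len(nT), drop = FALSE]

  n_min <- apply(Xs, 1, min)
  n_max <- apply(Xs, 1, max)
  mu <- rowMeans(Xs)
  n_std <- sqrt(rowMeans((Xs - mu)^2))

  thr <- if (is.null(gsl_threshold)) n_min + 0.2 * (n_max - n_min) else
    rep(gsl_threshold, npix)
  thr[n_max == n_min] <- -Inf           # constant series: full-year season
  n_gsl <- rowSums(Xy >= thr) / n_years

  t_idx <- seq_len(nT) - 1
  omega <- 2 * pi * n_years / nT
  cvec <- cos(omega * t_idx); svec <- sin(omega * t_idx)
  re <- as.vector(Xy %*% cvec)
  im <- as.vector(Xy %*% svec)          # -Im of the DFT component
  n_amplitude <- 2 * sqrt(re^2 + im^2) / nT
  n_phase <- atan2(im, re)

  mndvi <- rowMeans(X)
  sdndvi <- sqrt(rowMeans((X - rowMeans(X))^2))

  wrap <- function(v) {
    v[bad] <- NA_real_
    raster_grid(matrix(v, nrow(ref$values)), ref$transform, ref$crs)
  }
  list(n_min = wrap(n_min), n_max = wrap(n_max), n_std = wrap(n_std),
       n_gsl = wrap(n_gsl), n_amplitude = wrap(n_amplitude),
       n_phase = wrap(n_phase), mndvi = wrap(mndvi), sdndvi = wrap(sdndvi))
}
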