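# Orthonormal 2-D Haar discrete wavelet transform with recorded padding.
#
# Each level pads the current approximation plane to even row/column counts
# by symmetric (edge-reflective) extension, then splits it into LL, HL, LH
# and HH planes via the orthonormal Haar butterfly. The padding applied at
# every level is recorded so that reconstruction is exact and the final
# inverse can be cropped back to the source shape.

haar_level_forward <- function(x) {
  pad <- c(nrow(x) %% 2L, ncol(x) %% 2L)
  if (pad[1]) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (pad[2]) x <- cbind(x, x[, ncol(x), drop = FALSE])
  oi <- seq(1, nrow(x), by = 2); ei <- oi + 1
  oj <- seq(1, ncol(x), by = 2); ej <- oj + 1
  a <- x[oi, oj, drop = FALSE]; b <- x[oi, ej, drop = FALSE]
  c_ <- x[ei, oj, drop = FALSE]; d <- x[ei, ej, drop = FALSE]
  list(LL = (a + b + c_ + d) / 2,
       HL = (a - b + c_ - d) / 2,   # horizontal detail (column differences)
       LH = (a + b - c_ - d) / 2,   # vertical detail (row differences)
       HH = (a - b - c_ + d) / 2,
       pad = pad)
}

haar_level_inverse <- function(LL, HL, LH, HH, pad) {
  nr <- 2L * nrow(LL); nc <- 2L * ncol(LL)
  x <- matrix(0, nr, nc)
  oi <- seq(1, nr, by = 2); ei <- oi + 1
  oj <- seq(1, nc, by = 2); ej <- oj + 1
  x[oi, oj] <- (LL + HL + LH + HH) / 2
  x[oi, ej] <- (LL - HL + LH - HH) / 2
  x[ei, oj] <- (LL + HL - LH - HH) / 2
  x[ei, ej] <- (LL - HL - LH + HH) / 2
  if (pad[2]) x <- x[, -nc, drop = FALSE]
  if (pad[1]) x <- x[-nr, , drop = FALSE]
  x
}

#' Fusion configuration
#'
#' Bundles the tunable parameters of the wavelet fusion: decomposition depth,
#' wavelet basis, local-energy window, coefficient rules and the index of the
#' baseline (reference-date) image used for tie-breaking and spectral
#' reference.
#'
#' @param levels Number of cascading decompositions, in 1..4 (default 2).
#' @param wavelet Wavelet basis identifier; only `"haar"` is provided.
#' @param window Odd local-energy window edge length, >= 3 (default 3).
#' @param rule_low Rule for the deepest approximation (LL) plane:
#'   `"energy_weighted"` (default) or `"local_energy_max"`.
#' @param rule_high Rule for every detail (HL/LH/HH) plane:
#'   `"local_energy_max"` (default), `"energy_weighted"`, or `"mean"`.
#' @param baseline_index Index (into the fused image list) of the baseline
#'   acquisition, which wins local-energy ties.
#' @return An object of class `FusionConfig`.
#' @export
fusion_config <- function(levels = 2L, wavelet = "haar", window = 3L,
                          rule_low = c("energy_weighted", "local_energy_max"),
                          rule_high = c("local_energy_max", "energy_weighted",
                                        "mean"),
                          baseline_index = 1L) {
  rule_low <- match.arg(rule_low)
  rule_high <- match.arg(rule_high)
  levels <- as.integer(levels); window <- as.integer(window)
  if (levels < 1L || levels > 4L) stop("levels must be in [1, 4]")
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (wavelet != "haar") stop("unsupported wavelet: ", wavelet)
  structure(list(levels = levels, wavelet = wavelet, window = window,
                 rule_low = rule_low, rule_high = rule_high,
                 baseline_index = as.integer(baseline_index)),
            class = "FusionConfig")
}

#' Min-max normalize a band to [0, 1]
#'
#' Scales the unmasked cells of a band image onto \[0, 1\]; a constant image
#' maps to all zeros. Masked cells stay `NA` and are excluded from the
#' min/max.
#'
#' @param img A `RasterGrid` or numeric matrix.
#' @return A numeric matrix in \[0, 1\] (same shape; `NA` at masked cells).
#' @export
normalize_band <- function(img) {
  v <- if (inherits(img, "RasterGrid")) img$values else as.matrix(img)
  if (all(is.na(v))) stop("fully masked image cannot be normalized")
  rng <- range(v, na.rm = TRUE)
  if (rng[2] == rng[1]) {
    v[!is.na(v)] <- 0
    v
  } else {
    (v - rng[1]) / (rng[2] - rng[1])
  }
}

#' Image energy
#'
#' Sum of squared values over unmasked cells, E = sum(x_i^2): the information
#' density statistic driving the energy-weighted fusion of approximation
#' coefficients.
#'
#' @param x Numeric array or `RasterGrid`.
#' @return A nonnegative scalar.
#' @export
image_energy <- function(x) {
  v <- if (inherits(x, "RasterGrid")) x$values else x
  sum(v^2, na.rm = TRUE)
}

#' Normalized energy weights
#'
#' Weights W_i = E_i / sum_j(E_j), preserving order and summing to one.
#'
#' @param energies Nonnegative numeric vector with at least one positive
#'   entry.
#' @return Numeric weights summing to 1.
#' @export
energy_weights <- function(energies) {
  if (any(energies < 0) || any(!is.finite(energies)))
    stop("energies must be finite and nonnegative")
  total <- sum(energies)
  if (total == 0) stop("all energies are zero")
  energies / total
}

#' Decompose an image into a wavelet pyramid
#'
#' Cascading orthonormal Haar decomposition of the approximation chain.
#' Odd-sized planes are padded by edge reflection before each split and the
#' padding is recorded, so [dwt_reconstruct()] is exact.
#'
#' @param img Numeric matrix (or `RasterGrid`); must be at least
#'   `2^levels` in each dimension.
#' @param cfg A [fusion_config()].
#' @return An object of class `WaveletPyramid`: list of per-level
#'   `LL`/`HL`/`LH`/`HH` planes (the `LL` retained only at the deepest
#'   level), `wavelet_name`, `pad_record` and the source shape.
#' @export
dwt_decompose <- function(img, cfg = fusion_config()) {
  x <- if (inherits(img, "RasterGrid")) img$values else as.matrix(img)
  if (any(is.na(x))) stop("masked cells are not allowed in the transform")
  if (min(dim(x)) < 2^cfg$levels)
    stop(sprintf("image %dx%d too small for %d levels",
                 nrow(x), ncol(x), cfg$levels))
  levels <- vector("list", cfg$levels)
  pad_record <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels)) {
    dec <- haar_level_forward(x)
    levels[[l]] <- list(HL = dec$HL, LH = dec$LH, HH = dec$HH)
    pad_record[[l]] <- dec$pad
    x <- dec$LL
  }
  levels[[cfg$levels]]$LL <- x
  structure(list(levels = levels, wavelet_name = cfg$wavelet,
                 pad_record = pad_record,
                 shape = dim(if (inherits(img, "RasterGrid")) img$values
                             else as.matrix(img))),
            class = "WaveletPyramid")
}

#' Reconstruct an image from a wavelet pyramid
#'
#' Inverse of [dwt_decompose()]; reproduces the source within 1e-8 relative
#' error for an unmodified pyramid.
#'
#' @param pyr A `WaveletPyramid`.
#' @return Numeric matrix with the pyramid's recorded source shape.
#' @export
dwt_reconstruct <- function(pyr) {
  n <- length(pyr$levels)
  x <- pyr$levels[[n]]$LL
  for (l in rev(seq_len(n))) {
    lev <- pyr$levels[[l]]
    x <- haar_level_inverse(x, lev$HL, lev$LH, lev$HH, pyr$pad_record[[l]])
  }
  x
}

#' Local energy of a coefficient plane
#'
#' Per-position sum of squared coefficients over a centred odd window with
#' reflective edge padding; the statistic used to select detail coefficients.
#'
#' @param coeff Numeric matrix.
#' @param window Odd window edge length, at most `min(dim(coeff))`.
#' @return Numeric matrix of the same shape.
#' @export
local_energy <- function(coeff, window = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > min(dim(coeff))) stop("window larger than the plane")
  if (window == 1L) return(coeff^2)
  h <- (window - 1L) %/% 2L
  nr <- nrow(coeff); nc <- ncol(coeff)
  refl <- function(idx, n) {
    idx <- ifelse(idx < 1L, 2L - idx, idx)        # reflect about 1 (no repeat)
    ifelse(idx > n, 2L * n - idx, idx)
  }
  sq <- coeff^2
  padded <- sq[refl(seq(1L - h, nr + h), nr), refl(seq(1L - h, nc + h), nc),
               drop = FALSE]
  out <- matrix(0, nr, nc)
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L))
    out <- out + padded[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  out
}

#' Fuse wavelet pyramids
#'
#' Combines structurally identical pyramids from N source images into one.
#' Under the default rules the deepest approximation (LL) plane is the
#' energy-weighted mean of the sources (weights from [energy_weights()]),
#' while every detail plane takes, per position, the coefficient of the
#' source with the largest local energy; ties go to the baseline source,
#' then to the lowest index.
#'
#' @param pyramids List of `WaveletPyramid`s with equal structure.
#' @param cfg A [fusion_config()].
#' @param weights Energy weights for the sources; required for any
#'   energy-weighted rule.
#' @return A fused `WaveletPyramid`.
#' @export
fuse_coefficients <- function(pyramids, cfg = fusion_config(), weights = NULL) {
  n <- length(pyramids)
  if (n == 0) stop("empty pyramid list")
  ref <- pyramids[[1]]
  for (i in seq_len(n)[-1]) {
    p <- pyramids[[i]]
    if (length(p$levels) != length(ref$levels) ||
        !identical(p$wavelet_name, ref$wavelet_name) ||
        !identical(dim(p$levels[[1]]$HH), dim(ref$levels[[1]]$HH)))
      stop("pyramids 1 and ", i, " differ in structure")
  }
  if (is.null(weights)) weights <- rep(1 / n, n)

  plane_stack <- function(extract) lapply(pyramids, extract)

  weighted_mean_plane <- function(planes, w) {
    out <- planes[[1]] * w[1]
    for (i in seq_along(planes)[-1]) out <- out + planes[[i]] * w[i]
    out
  }
  # per-position argmax of local energy; ties -> baseline, then lowest index
  select_plane <- function(planes) {
    if (n == 1L) return(planes[[1]])
    # deep levels can be smaller than the window: clamp to the largest odd
    # width that fits so the rule degrades gracefully to per-cell energy
    w <- min(cfg$window, min(dim(planes[[1]])))
    if (w %% 2L == 0L) w <- w - 1L
    le <- lapply(planes, local_energy, window = max(w, 1L))
    best_val <- le[[1]]
    pick <- matrix(1L, nrow(best_val), ncol(best_val))
    for (i in seq_len(n)[-1]) {
      better <- le[[i]] > best_val
      if (i == cfg$baseline_index) better <- le[[i]] >= best_val
      pick[better] <- i
      best_val[better] <- le[[i]][better]
    }
    # the baseline also retakes exact ties against earlier non-baseline picks
    if (cfg$baseline_index > 1L && cfg$baseline_index <= n) {
      tie <- le[[cfg$baseline_index]] == best_val
      pick[tie] <- cfg$baseline_index
    }
    out <- planes[[1]]
    for (i in seq_len(n)) {
      sel <- pick == i
      out[sel] <- planes[[i]][sel]
    }
    out
  }
  apply_rule <- function(planes, rule) {
    switch(rule,
           energy_weighted = weighted_mean_plane(planes, weights),
           local_energy_max = select_plane(planes),
           mean = weighted_mean_plane(planes, rep(1 / n, n)),
           stop("unknown rule: ", rule))
  }

  fused <- ref
  nlev <- length(ref$levels)
  for (l in seq_len(nlev)) {
    for (sub in c("HL", "LH", "HH")) {
      fused$levels[[l]][[sub]] <-
        apply_rule(plane_stack(function(p) p$levels[[l]][[sub]]), cfg$rule_high)
    }
  }
  fused$levels[[nlev]]$LL <-
    apply_rule(plane_stack(function(p) p$levels[[nlev]]$LL), cfg$rule_low)
  fused
}

#' Local-energy-weighted DWT fusion of co-registered images
#'
#' The full fusion chain for one spectral band across acquisition dates:
#' min-max normalize each image, compute its global energy, decompose each
#' into a Haar pyramid, fuse coefficients (energy-weighted approximation,
#' local-energy-selected details) and invert the transform. The output stays
#' in normalized \[0, 1\] space unless `rescale_to_baseline` is set, in which
#' case it is affinely mapped to the baseline image's value range.
#'
#' @param images List of co-registered `RasterGrid`s (one per date); a
#'   single image returns its normalized self.
#' @param cfg A [fusion_config()].
#' @param rescale_to_baseline Rescale the fused band to the baseline image's
#'   min/max for visualization (default `FALSE`).
#' @return A `RasterGrid` with the input geometry.
#' @export
lew_dwt_fuse <- function(images, cfg = fusion_config(),
                         rescale_to_baseline = FALSE) {
  if (length(images) == 0) stop("no images to fuse")
  assert_coregistered(images)
  if (any(vapply(images, function(g) all(g$mask), logical(1))))
    stop("fully masked images cannot be fused")
  norm <- lapply(images, normalize_band)
  energies <- vapply(norm, image_energy, numeric(1))
  w <- energy_weights(energies)
  pyramids <- lapply(norm, fill_masked_then_decompose, cfg = cfg)
  fused_pyr <- fuse_coefficients(pyramids, cfg, weights = w)
  out <- dwt_reconstruct(fused_pyr)
  if (rescale_to_baseline) {
    base <- images[[cfg$baseline_index]]$values
    rng <- range(base, na.rm = TRUE)
    out <- rng[1] + out * (rng[2] - rng[1])
  }
  ref <- images[[1]]
  out[joint_mask(images)] <- NA_real_
  raster_grid(out, ref$transform, ref$crs)
}

#' Baseline fusion strategies
#'
#' Control methods for the fusion comparison: `"traditional_dwt"` fuses all
#' coefficient planes (approximation and detail) by the unweighted mean rule
#' and inverts the transform; `"simple_splicing"` performs no fusion at all
#' and returns the normalized input bands as a stack for direct feature
#' concatenation.
#'
#' @param images List of co-registered `RasterGrid`s.
#' @param method `"traditional_dwt"` or `"simple_splicing"`.
#' @param cfg A [fusion_config()] (used by `"traditional_dwt"`).
#' @return A `RasterGrid` (`traditional_dwt`) or list of `RasterGrid`s
#'   (`simple_splicing`).
#' @export
fuse_baseline <- function(images, method = c("traditional_dwt",
                                             "simple_splicing"),
                          cfg = fusion_config()) {
  method <- match.arg(method)
  if (length(images) == 0) stop("no images to fuse")
  assert_coregistered(images)
  if (method == "simple_splicing") {
    return(lapply(images, function(g)
      raster_grid(normalize_band(g), g$transform, g$crs)))
  }
  cfg$rule_low <- "energy_weighted"
  cfg$rule_high <- "mean"
  norm <- lapply(images, normalize_band)
  pyramids <- lapply(norm, fill_masked_then_decompose, cfg = cfg)
  n <- length(images)
  fused_pyr <- fuse_coefficients(pyramids, cfg, weights = rep(1 / n, n))
  out <- dwt_reconstruct(fused_pyr)
  ref <- images[[1]]
  out[joint_mask(images)] <- NA_real_
  raster_grid(out, ref$transform, ref$crs)
}

# Union of the input nodata masks: a fused cell is masked as soon as any
# source date is masked there.
joint_mask <- function(images) {
  m <- images[[1]]$mask
  for (i in seq_along(images)[-1]) m <- m | images[[i]]$mask
  m
}

# Partially masked bands enter the transform with masked cells filled by the
# band's unmasked mean; the joint mask is re-applied after reconstruction.
fill_masked_then_decompose <- function(x, cfg) {
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  dwt_decompose(x, cfg)
}
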