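# Fusion quality metrics: spectral angle mapper (SAM), information entropy
# (IE) and average gradient (AG). The conventional definitions from the
# fusion-quality literature are used: mean per-pixel arccos of the spectral
# cosine for SAM, Shannon entropy of a 256-level min-max quantization for IE,
# and the forward-difference sqrt((dx^2 + dy^2) / 2) mean for AG.

as_band_matrix <- function(x) {
  if (inherits(x, "RasterGrid")) x$values else as.matrix(x)
}

#' Spectral angle between two multi-band images
#'
#' Mean over unmasked pixels of the angle between the per-pixel spectra of a
#' fused image and a reference image, in radians. Spectral distortion metric:
#' 0 means identical (up to per-pixel positive scaling) spectra. Pixels whose
#' spectrum has zero norm in either image, or is masked in any band, are
#' excluded.
#'
#' @param fused,reference Lists of co-registered `RasterGrid`s (or numeric
#'   matrices), one element per band; at least two bands.
#' @return Mean spectral angle in radians, in \[0, pi\].
#' @export
spectral_angle <- function(fused, reference) {
  if (length(fused) != length(reference))
    stop("band count mismatch: ", length(fused), " vs ", length(reference))
  if (length(fused) < 2) stop("spectral angle needs at least 2 bands")
  f <- vapply(fused, function(b) as.vector(as_band_matrix(b)),
              numeric(length(as_band_matrix(fused[[1]]))))
  r <- vapply(reference, function(b) as.vector(as_band_matrix(b)),
              numeric(length(as_band_matrix(reference[[1]]))))
  ok <- stats::complete.cases(f) & stats::complete.cases(r)
  nf <- sqrt(rowSums(f^2)); nr <- sqrt(rowSums(r^2))
  ok <- ok & nf > 0 & nr > 0
  if (!any(ok)) stop("no usable pixels for the spectral angle")
  cosang <- rowSums(f * r)[ok] / (nf[ok] * nr[ok])
  mean(acos(pmin(pmax(cosang, -1), 1)))
}

#' Information entropy of an image
#'
#' Min-max quantizes the unmasked cells to `bins` levels and returns the
#' Shannon entropy of the level histogram in bits. Invariant to affine
#' rescaling of the values; a constant image has entropy 0, and an image
#' occupying all levels uniformly reaches `log2(bins)`.
#'
#' @param img `RasterGrid` or numeric matrix.
#' @param bins Number of quantization levels (default 256).
#' @return Entropy in bits, in \[0, log2(bins)\].
#' @export
information_entropy <- function(img, bins = 256L) {
  v <- as.vector(as_band_matrix(img))
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no unmasked cells")
  rng <- range(v)
  if (rng[2] == rng[1]) return(0)
  lev <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins), bins - 1L)
  p <- tabulate(lev + 1L, nbins = bins)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

#' Average gradient of an image
#'
#' Sharpness/texture measure: the mean over the (n-1) x (m-1) interior of
#' sqrt((dx^2 + dy^2) / 2) with forward differences dx along columns and dy
#' along rows. A constant image scores 0; a unit-slope ramp scores
#' sqrt(1/2).
#'
#' @param img `RasterGrid` or numeric matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
average_gradient <- function(img) {
  v <- as_band_matrix(img)
  if (nrow(v) < 2 || ncol(v) < 2) stop("image must be at least 2x2")
  nr <- nrow(v); nc <- ncol(v)
  core <- v[-nr, -nc, drop = FALSE]
  dx <- v[-nr, -1, drop = FALSE] - core
  dy <- v[-1, -nc, drop = FALSE] - core
  mean(sqrt((dx^2 + dy^2) / 2), na.rm = TRUE)
}

#' Quality report for a fused product
#'
#' Computes the three fusion quality metrics for a fused multi-band stack
#' against a reference (baseline-date) stack: SAM (multi-band), and IE and AG
#' per band with their band means.
#'
#' @param fused,reference Lists of co-registered `RasterGrid`s (one per
#'   band).
#' @param bins Entropy quantization levels.
#' @return A list of class `QualityReport` with `sam_radians`,
#'   `entropy_bits` (per band + `mean`), `avg_gradient` (per band + `mean`).
#' @export
fusion_quality <- function(fused, reference, bins = 256L) {
  ie <- vapply(fused, information_entropy, numeric(1), bins = bins)
  ag <- vapply(fused, average_gradient, numeric(1))
  structure(list(sam_radians = spectral_angle(fused, reference),
                 entropy_bits = list(per_band = ie, mean = mean(ie)),
                 avg_gradient = list(per_band = ag, mean = mean(ag))),
            class = "QualityReport")
}
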