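# RasterGrid: a single 2-D band with grid geometry and a nodata mask.
#
# Grid convention: pixel-is-area, origin at the upper-left corner, row-major
# storage (row 1 = northernmost). The affine transform is the vector
# c(x0, y0, px, py) with px, py > 0: the centre of pixel (i, j) sits at
# x = x0 + (j - 0.5) * px, y = y0 - (i - 0.5) * py. Point-to-pixel mapping
# uses half-open pixel intervals. All arithmetic is double precision; files
# are written float32 by default.

#' Construct a RasterGrid
#'
#' A `RasterGrid` couples a 2-D matrix of values with affine grid geometry,
#' a coordinate reference system identifier and a nodata mask. Masked cells
#' hold `NA` in `values` and are excluded from every downstream statistic.
#'
#' @param values Numeric matrix (rows x cols).
#' @param transform Numeric length-4 vector `c(x0, y0, px, py)`: map
#'   coordinates of the upper-left grid corner and the (strictly positive)
#'   pixel width and height in map units (metres for projected grids).
#' @param crs Coordinate reference system identifier, e.g. `"EPSG:32650"`.
#' @param mask Optional logical matrix, `TRUE` marking nodata cells. Defaults
#'   to `is.na(values)`.
#' @return An object of class `RasterGrid`.
#' @examples
#' g <- raster_grid(matrix(1:4, 2), c(500000, 4000000, 30, 30), "EPSG:32650")
#' dim(g$values)
#' @export
raster_grid <- function(values, transform, crs, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(length(transform) == 4, nrow(values) >= 1, ncol(values) >= 1)
  if (transform[3] <= 0 || transform[4] <= 0)
    stop("pixel size must be strictly positive")
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values)))
    stop("values and nodata mask must have identical shape")
  values[mask] <- NA_real_
  structure(list(values = values, transform = as.numeric(transform),
                 crs = as.character(crs), mask = mask),
            class = "RasterGrid")
}

#' @export
print.RasterGrid <- function(x, ...) {
  cat(sprintf("RasterGrid %d x %d, pixel %g x %g, crs %s, %d masked cells\n",
              nrow(x$values), ncol(x$values), x$transform[3], x$transform[4],
              x$crs, sum(x$mask)))
  invisible(x)
}

#' Grid geometry of a raster
#'
#' @param grid A `RasterGrid`, or the elements of a geometry given directly.
#' @param nrow,ncol,transform,crs Geometry components when `grid` is missing.
#' @return A list with `nrow`, `ncol`, `transform`, `crs`.
#' @export
grid_geometry <- function(grid = NULL, nrow = NULL, ncol = NULL,
                          transform = NULL, crs = NULL) {
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "RasterGrid"))
    list(nrow = nrow(grid$values), ncol = ncol(grid$values),
         transform = grid$transform, crs = grid$crs)
  } else {
    list(nrow = nrow, ncol = ncol, transform = as.numeric(transform),
         crs = as.character(crs))
  }
}

epsg_code <- function(crs) {
  m <- regmatches(crs, regexpr("[0-9]+$", crs))
  if (length(m) == 0) NA_integer_ else as.integer(m)
}

#' Read a GeoTIFF raster
#'
#' Reads a single- or multi-band GeoTIFF; nodata cells (per the file's nodata
#' tag) are translated into the mask, and values are returned as doubles.
#'
#' @param path Path to a GeoTIFF file.
#' @return A `RasterGrid` for a single-band file, otherwise a list of
#'   `RasterGrid`s, one per band, sharing geometry.
#' @seealso [write_raster()]
#' @export
read_raster <- function(path) {
  g <- geotiff_read(path)
  if (is.null(g$pixel_scale) || is.null(g$tiepoint))
    stop("no georeferencing in file: ", path)
  if (is.na(g$epsg))
    stop("CRS absent in file: ", path)
  transform <- c(g$tiepoint[4], g$tiepoint[5], g$pixel_scale[1], g$pixel_scale[2])
  crs <- paste0("EPSG:", g$epsg)
  bands <- lapply(seq_len(g$n_bands), function(b) {
    v <- g$values[, , b, drop = TRUE]
    if (!is.na(g$nodata)) v[v == g$nodata] <- NA_real_
    raster_grid(v, transform, crs)
  })
  if (length(bands) == 1L) bands[[1]] else bands
}

#' Write a GeoTIFF raster
#'
#' @param grid A `RasterGrid` or a list of co-registered `RasterGrid`s
#'   (written as one multi-band file).
#' @param path Output path.
#' @param nodata Nodata value substituted for masked cells.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999, datatype = "float32") {
  grids <- if (inherits(grid, "RasterGrid")) list(grid) else grid
  assert_coregistered(grids)
  g1 <- grids[[1]]
  values <- array(NA_real_, c(nrow(g1$values), ncol(g1$values), length(grids)))
  for (b in seq_along(grids)) values[, , b] <- grids[[b]]$values
  geotiff_write(values, path,
                pixel_scale = g1$transform[3:4], origin = g1$transform[1:2],
                epsg = epsg_code(g1$crs), nodata = nodata, datatype = datatype)
}

#' Check that rasters share one analysis grid
#'
#' Passes iff all grids have equal shape, transform and CRS; otherwise raises
#' an error naming the first offending pair.
#'
#' @param grids List of `RasterGrid`s (at least one).
#' @return `TRUE`, invisibly.
#' @export
assert_coregistered <- function(grids) {
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    g <- grids[[i]]
    if (!identical(dim(g$values), dim(ref$values)))
      stop(sprintf("grids 1 and %d differ in shape (%dx%d vs %dx%d)", i,
                   nrow(ref$values), ncol(ref$values),
                   nrow(g$values), ncol(g$values)))
    if (!isTRUE(all.equal(g$transform, ref$transform, tolerance = 1e-9)))
      stop(sprintf("grids 1 and %d differ in transform", i))
    if (!identical(g$crs, ref$crs))
      stop(sprintf("grids 1 and %d differ in CRS (%s vs %s)", i, ref$crs, g$crs))
  }
  invisible(TRUE)
}

# Keys cubic-convolution kernel (a = -0.5), the resampling kernel used for
# continuous covariates.
cubic_kernel <- function(s) {
  s <- abs(s)
  a <- -0.5
  ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
         ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
}

raster_extent <- function(geom) {
  c(xmin = geom$transform[1],
    xmax = geom$transform[1] + geom$ncol * geom$transform[3],
    ymax = geom$transform[2],
    ymin = geom$transform[2] - geom$nrow * geom$transform[4])
}

#' Resample a raster onto a target grid
#'
#' Continuous variables use cubic-convolution interpolation; categorical
#' variables use nearest-neighbour resampling (which never invents values).
#' Source and target must share a CRS; reprojection is the caller's duty.
#'
#' @param src A `RasterGrid`.
#' @param target A grid geometry from [grid_geometry()].
#' @param kind `"continuous"` or `"categorical"`.
#' @return A `RasterGrid` on the target geometry.
#' @export
resample_to_grid <- function(src, target, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!identical(src$crs, target$crs))
    stop("source and target CRS differ (", src$crs, " vs ", target$crs, ")")
  es <- raster_extent(grid_geometry(src))
  et <- raster_extent(target)
  if (et["xmin"] >= es["xmax"] || et["xmax"] <= es["xmin"] ||
      et["ymin"] >= es["ymax"] || et["ymax"] <= es["ymin"])
    stop("source and target extents do not overlap")

  nr <- target$nrow; nc <- target$ncol
  xt <- target$transform[1] + (seq_len(nc) - 0.5) * target$transform[3]
  yt <- target$transform[2] - (seq_len(nr) - 0.5) * target$transform[4]
  # fractional (1-based, centre-of-pixel) source coordinates of target centres
  cx <- (xt - src$transform[1]) / src$transform[3] + 0.5
  cy <- (src$transform[2] - yt) / src$transform[4] + 0.5
  sr <- nrow(src$values); sc <- ncol(src$values)

  out <- matrix(NA_real_, nr, nc)
  if (kind == "categorical") {
    ri <- pmin(pmax(round(cy), 1), sr)
    ci <- pmin(pmax(round(cx), 1), sc)
    out <- matrix(src$values[cbind(rep(ri, times = nc),
                                   rep(ci, each = nr))], nr, nc)
  } else {
    v <- src$values
    clamp <- function(idx, n) pmin(pmax(idx, 1L), n)
    r0 <- floor(cy); c0 <- floor(cx)
    for (dr in -1:2) {
      wr <- cubic_kernel(cy - (r0 + dr))           # length nr
      rows <- clamp(as.integer(r0 + dr), sr)
      for (dc in -1:2) {
        wc <- cubic_kernel(cx - (c0 + dc))         # length nc
        cols <- clamp(as.integer(c0 + dc), sc)
        contrib <- v[rows, cols, drop = FALSE] *
          outer(wr, wc)
        out <- if (dr == -1 && dc == -1) contrib else out + contrib
      }
    }
  }
  raster_grid(out, target$transform, target$crs)
}
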