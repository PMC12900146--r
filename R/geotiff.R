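# Minimal classic-TIFF / GeoTIFF reader and writer.
#
# Scope: uncompressed, strip-organised, chunky (pixel-interleaved) rasters with
# 8/16/32/64-bit unsigned, signed or IEEE-float samples, plus the GeoTIFF
# georeferencing tags (ModelPixelScale, ModelTiepoint, GeoKeyDirectory) and the
# GDAL_NODATA convention. This covers every raster the toolkit writes and the
# band-interleaved GeoTIFFs common GIS stacks produce for single-resolution
# imagery. BigTIFF, tiling and compression are out of scope.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L,
                    `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

tiff_read_values <- function(con, type, count, endian) {
  size <- TIFF_TYPE_SIZE[as.character(type)]
  if (is.na(size)) stop("unsupported TIFF field type: ", type)
  if (type %in% c(1L, 2L, 6L)) {
    raw <- readBin(con, "raw", n = count)
    if (type == 2L) rawToChar(raw[raw != as.raw(0)]) else {
      v <- as.integer(raw)
      if (type == 6L) ifelse(v > 127L, v - 256L, v) else v
    }
  } else if (type == 3L) {
    readBin(con, "integer", n = count, size = 2L, signed = FALSE, endian = endian)
  } else if (type == 8L) {
    readBin(con, "integer", n = count, size = 2L, signed = TRUE, endian = endian)
  } else if (type %in% c(4L, 9L)) {
    readBin(con, "integer", n = count, size = 4L, endian = endian)
  } else if (type == 11L) {
    readBin(con, "double", n = count, size = 4L, endian = endian)
  } else { # 12: double
    readBin(con, "double", n = count, size = 8L, endian = endian)
  }
}

tiff_read_ifd <- function(con, endian) {
  n_entries <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  entries <- list()
  for (i in seq_len(n_entries)) {
    tag   <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    type  <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", size = 4L, endian = endian)
    here  <- seek(con, NA)
    size  <- TIFF_TYPE_SIZE[as.character(type)]
    if (!is.na(size) && size * count <= 4) {
      val <- tiff_read_values(con, type, count, endian)
      seek(con, here + 4)
    } else {
      offset <- readBin(con, "integer", size = 4L, endian = endian)
      after <- seek(con, NA)
      seek(con, offset)
      val <- tiff_read_values(con, type, count, endian)
      seek(con, after)
    }
    entries[[as.character(tag)]] <- val
  }
  next_ifd <- readBin(con, "integer", size = 4L, endian = endian)
  list(entries = entries, next_ifd = next_ifd)
}

tiff_tag <- function(ifd, tag, default = NULL) {
  v <- ifd[[as.character(tag)]]
  if (is.null(v)) default else v
}

#' Read a GeoTIFF file into raw arrays and georeferencing metadata
#'
#' Low-level reader used by [read_raster()]. Returns pixel values as a numeric
#' array plus the affine transform, CRS code and nodata value, without applying
#' any masking.
#'
#' @param path Path to a classic (non-Big) TIFF file with uncompressed strips.
#' @return A list with elements `values` (rows x cols x bands array), `nrow`,
#'   `ncol`, `n_bands`, `pixel_scale`, `tiepoint`, `epsg` (integer or `NA`),
#'   and `nodata` (numeric or `NA`).
#' @keywords internal
geotiff_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(order_bytes, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a classic TIFF file: ", path)
  ifd_offset <- readBin(con, "integer", size = 4L, endian = endian)

  planes <- list()
  meta <- NULL
  while (ifd_offset != 0L) {
    seek(con, ifd_offset)
    ifd <- tiff_read_ifd(con, endian)
    e <- ifd$entries
    width  <- tiff_tag(e, 256)
    height <- tiff_tag(e, 257)
    spp    <- tiff_tag(e, 277, 1L)
    bits   <- tiff_tag(e, 258, 1L)[1]
    fmt    <- tiff_tag(e, 339, 1L)[1]
    comp   <- tiff_tag(e, 259, 1L)
    planar <- tiff_tag(e, 284, 1L)
    if (comp != 1L) stop("unsupported TIFF compression (", comp, ") in ", path)
    if (planar != 1L) stop("unsupported planar configuration in ", path)
    offsets <- tiff_tag(e, 273)
    counts  <- tiff_tag(e, 279)
    if (is.null(offsets)) stop("tiled or stripless TIFF not supported: ", path)
    n_vals <- as.numeric(width) * height * spp
    what <- if (fmt == 3L) "double" else "integer"
    size <- bits %/% 8L
    signed <- fmt == 2L
    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      n_s <- counts[s] %/% size
      if (size %in% c(1L, 2L) && !signed) {
        vals <- c(vals, readBin(con, "integer", n = n_s, size = size,
                                signed = FALSE, endian = endian))
      } else if (what == "integer") {
        vals <- c(vals, readBin(con, "integer", n = n_s, size = size,
                                endian = endian))
      } else {
        vals <- c(vals, readBin(con, "double", n = n_s, size = size,
                                endian = endian))
      }
    }
    if (length(vals) < n_vals) stop("truncated TIFF data in ", path)
    vals <- vals[seq_len(n_vals)]
    arr <- aperm(array(vals, dim = c(spp, width, height)), c(3L, 2L, 1L))
    if (is.null(meta)) {
      scale <- tiff_tag(e, 33550)
      tie   <- tiff_tag(e, 33922)
      keys  <- tiff_tag(e, 34735)
      nodata_str <- tiff_tag(e, 42113)
      epsg <- NA_integer_
      if (!is.null(keys) && length(keys) >= 4) {
        n_keys <- keys[4]
        for (k in seq_len(n_keys)) {
          key <- keys[4 * k + 1]
          if (key %in% c(3072L, 2048L)) epsg <- keys[4 * k + 4]
        }
      }
      meta <- list(pixel_scale = scale, tiepoint = tie, epsg = epsg,
                   nodata = if (is.null(nodata_str)) NA_real_ else
                     suppressWarnings(as.numeric(nodata_str)))
    }
    planes <- c(planes, lapply(seq_len(spp), function(b) arr[, , b, drop = TRUE]))
    ifd_offset <- ifd$next_ifd
  }
  n_bands <- length(planes)
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  values <- array(unlist(planes, use.names = FALSE), dim = c(h, w, n_bands))
  for (b in seq_len(n_bands)) values[, , b] <- planes[[b]]
  c(list(values = values, nrow = h, ncol = w, n_bands = n_bands), meta)
}

tiff_pack_values <- function(values, type, endian) {
  if (type == 2L) {
    raw <- c(charToRaw(values), as.raw(0))
    raw
  } else if (type == 3L) {
    writeBin(as.integer(values), raw(), size = 2L, endian = endian)
  } else if (type == 4L) {
    writeBin(as.integer(values), raw(), size = 4L, endian = endian)
  } else if (type == 11L) {
    writeBin(as.numeric(values), raw(), size = 4L, endian = endian)
  } else if (type == 12L) {
    writeBin(as.numeric(values), raw(), size = 8L, endian = endian)
  } else stop("unsupported write type ", type)
}

#' Write a GeoTIFF file from a numeric array
#'
#' Low-level writer used by [write_raster()]. Writes a single-IFD,
#' pixel-interleaved, uncompressed classic TIFF with GeoTIFF georeferencing
#' tags and the GDAL nodata convention.
#'
#' @param values Numeric matrix (rows x cols) or rows x cols x bands array.
#' @param path Output file path.
#' @param pixel_scale Length-2 numeric, pixel width and height in map units.
#' @param origin Length-2 numeric, map coordinates of the upper-left corner.
#' @param epsg Integer EPSG code, or `NA` to omit the CRS keys.
#' @param nodata Numeric nodata value recorded in the GDAL_NODATA tag; cells
#'   equal to `NA` in `values` are written as this value.
#' @param datatype `"float32"` or `"float64"` storage.
#' @return `path`, invisibly.
#' @keywords internal
geotiff_write <- function(values, path, pixel_scale, origin, epsg = NA,
                          nodata = -9999, datatype = "float32") {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  h <- dim(values)[1]; w <- dim(values)[2]; spp <- dim(values)[3]
  values[is.na(values)] <- nodata
  sample_size <- if (datatype == "float64") 8L else 4L
  endian <- "little"

  pixel_stream <- as.vector(aperm(values, c(3L, 2L, 1L)))
  data_raw <- writeBin(as.numeric(pixel_stream), raw(), size = sample_size,
                       endian = endian)

  geokeys <- c(1L, 1L, 0L, 2L,
               1024L, 0L, 1L, 1L,    # model type: projected
               1025L, 0L, 1L, 1L)    # raster type: pixel-is-area
  if (!is.na(epsg)) {
    geokeys[4] <- 3L
    geokeys <- c(geokeys, 3072L, 0L, 1L, as.integer(epsg))
  }
  nodata_str <- format(nodata, scientific = FALSE, trim = TRUE)

  tags <- list(
    list(tag = 256L, type = 4L, values = w),
    list(tag = 257L, type = 4L, values = h),
    list(tag = 258L, type = 3L, values = rep(8L * sample_size, spp)),
    list(tag = 259L, type = 3L, values = 1L),
    list(tag = 262L, type = 3L, values = 1L),
    list(tag = 273L, type = 4L, values = NA),   # patched below
    list(tag = 277L, type = 3L, values = spp),
    list(tag = 278L, type = 4L, values = h),
    list(tag = 279L, type = 4L, values = length(data_raw)),
    list(tag = 284L, type = 3L, values = 1L),
    list(tag = 339L, type = 3L, values = rep(3L, spp)),   # IEEE float samples
    list(tag = 33550L, type = 12L, values = c(pixel_scale[1], pixel_scale[2], 0)),
    list(tag = 33922L, type = 12L, values = c(0, 0, 0, origin[1], origin[2], 0)),
    list(tag = 34735L, type = 3L, values = geokeys),
    list(tag = 42113L, type = 2L, values = nodata_str)
  )

  header_size <- 8L
  data_offset <- header_size
  ifd_offset <- data_offset + length(data_raw)
  n_tags <- length(tags)
  ifd_size <- 2L + n_tags * 12L + 4L
  overflow_offset <- ifd_offset + ifd_size

  tags[[6]]$values <- data_offset

  overflow <- raw(0)
  entry_raw <- raw(0)
  for (t in tags) {
    packed <- tiff_pack_values(t$values, t$type, endian)
    count <- if (t$type == 2L) length(packed) else length(t$values)
    entry <- c(writeBin(t$tag, raw(), size = 2L, endian = endian),
               writeBin(t$type, raw(), size = 2L, endian = endian),
               writeBin(as.integer(count), raw(), size = 4L, endian = endian))
    if (length(packed) <= 4L) {
      entry <- c(entry, packed, raw(4L - length(packed)))
    } else {
      entry <- c(entry, writeBin(as.integer(overflow_offset + length(overflow)),
                                 raw(), size = 4L, endian = endian))
      overflow <- c(overflow, packed)
    }
    entry_raw <- c(entry_raw, entry)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2L, endian = endian)
  writeBin(as.integer(ifd_offset), con, size = 4L, endian = endian)
  writeBin(data_raw, con)
  writeBin(as.integer(n_tags), con, size = 2L, endian = endian)
  writeBin(entry_raw, con)
  writeBin(0L, con, size = 4L, endian = endian)
  writeBin(overflow, con)
  invisible(path)
}
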