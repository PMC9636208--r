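#' Whole-slide image container
#'
#' Wraps an RGB 8-bit raster together with its physical pixel size. Pixels
#' are stored as an integer array of dimension `height x width x 3` with
#' values in 0..255, row-major with the origin at the top-left corner
#' (x = column, y = row).
#'
#' @param pixels integer array `h x w x 3`, values in 0..255.
#' @param um_per_pixel positive numeric, physical pixel size in micrometres.
#' @param source_path optional path the raster was read from.
#' @return An object of class `wsi`.
#' @export
wsi <- function(pixels, um_per_pixel, source_path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an h x w x 3 array (RGB)")
  if (!is.numeric(um_per_pixel) || length(um_per_pixel) != 1L ||
      !is.finite(um_per_pixel) || um_per_pixel <= 0)
    stop("`um_per_pixel` must be a single positive number")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must be integers in 0..255")
  structure(
    list(pixels = pixels,
         width_px = dim(pixels)[2], height_px = dim(pixels)[1],
         um_per_pixel = as.numeric(um_per_pixel),
         source_path = source_path),
    class = "wsi")
}

#' @export
print.wsi <- function(x, ...) {
  cat(sprintf("<wsi> %d x %d px, %.4g um/px%s\n", x$width_px, x$height_px,
              x$um_per_pixel,
              if (is.na(x$source_path)) "" else paste0(" [", x$source_path, "]")))
  invisible(x)
}

## [0,1] float array (as returned by png/tiff readers) -> 0..255 integer h x w x 3
.float_to_rgb8 <- function(a) {
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))  # grey -> RGB
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]             # drop alpha
  if (dim(a)[3] == 2L) a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  array(as.integer(round(pmin(pmax(a, 0), 1) * 255)), dim = dim(a))
}

## micrometres per pixel from readTIFF(info = TRUE) attributes, or NA
.tiff_um_per_pixel <- function(img) {
  xres <- attr(img, "x.resolution")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NA_real_)
  unit <- attr(img, "resolution.unit")
  per_um <- switch(as.character(unit %||% "inch"),
                   inch = xres / 25400, cm = xres / 10000, NA_real_)
  if (is.na(per_um) || per_um <= 0) NA_real_ else 1 / per_um
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a slide raster
#'
#' Reads a PNG or TIFF image as a [wsi]. The physical pixel size is resolved
#' in this order: the `um_per_pixel` argument, TIFF resolution tags, then a
#' JSON sidecar `<path>.json` with a `um_per_pixel` field (written by
#' [write_slide] and [make_cohort]). It is never guessed.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param um_per_pixel optional positive numeric override.
#' @return A [wsi].
#' @export
read_slide <- function(path, um_per_pixel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  um_meta <- NA_real_
  if (ext %in% c("tif", "tiff")) {
    img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop("cannot decode TIFF: ", path))
    um_meta <- .tiff_um_per_pixel(img)
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop("cannot decode PNG: ", path))
  } else stop("unsupported slide format: .", ext, " (use PNG or TIFF)")
  um <- if (!is.null(um_per_pixel)) um_per_pixel else um_meta
  if (is.na(um)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$um_per_pixel)) um <- as.numeric(meta$um_per_pixel)
    }
  }
  if (is.na(um))
    stop("no um/pixel metadata in ", path,
         " and no `um_per_pixel` override given")
  wsi(.float_to_rgb8(img), um, source_path = path)
}

#' Write a slide raster
#'
#' PNG output is accompanied by a JSON sidecar carrying `um_per_pixel` (PNG
#' has no physical-resolution field). TIFF output is baseline uncompressed
#' RGB with XResolution/YResolution tags set in pixels per centimetre.
#'
#' @param slide a [wsi].
#' @param path destination (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "wsi"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(slide$pixels / 255, path)
    jsonlite::write_json(list(um_per_pixel = slide$um_per_pixel),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("tif", "tiff")) {
    .write_baseline_tiff(slide$pixels, path, slide$um_per_pixel)
  } else stop("unsupported slide format: .", ext)
  invisible(path)
}

## Minimal baseline TIFF encoder: single strip, uncompressed 8-bit RGB,
## little-endian, with resolution tags (ResolutionUnit = cm).
.write_baseline_tiff <- function(pixels, path, um_per_pixel) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  ## interleave RGB row-major
  px <- aperm(pixels, c(3, 2, 1))            # channel, col, row
  raw_data <- as.raw(as.vector(px))
  n_tags <- 12L
  ## layout: header (8) | pixel data | XRes rational (8) | YRes rational (8)
  ##         | BitsPerSample triple (6) | IFD
  off_data <- 8L
  off_xres <- off_data + length(raw_data)
  off_yres <- off_xres + 8L
  off_bps  <- off_yres + 8L
  off_ifd  <- off_bps + 6L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42L), con, size = 2, endian = "little")
  writeBin(as.integer(off_ifd), con, size = 4, endian = "little")
  writeBin(raw_data, con)
  ppcm <- 10000 / um_per_pixel               # pixels per centimetre
  writeBin(as.integer(round(ppcm * 1000)), con, size = 4, endian = "little")
  writeBin(1000L, con, size = 4, endian = "little")
  writeBin(as.integer(round(ppcm * 1000)), con, size = 4, endian = "little")
  writeBin(1000L, con, size = 4, endian = "little")
  writeBin(as.integer(c(8L, 8L, 8L)), con, size = 2, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {         # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(as.integer(n_tags), con, size = 2, endian = "little")
  tag(256, 4, 1, w)                   # ImageWidth
  tag(257, 4, 1, h)                   # ImageLength
  tag(258, 3, 3, off_bps)             # BitsPerSample
  tag(259, 3, 1, 1)                   # Compression: none
  tag(262, 3, 1, 2)                   # Photometric: RGB
  tag(273, 4, 1, off_data)            # StripOffsets
  tag(277, 3, 1, 3)                   # SamplesPerPixel
  tag(278, 4, 1, h)                   # RowsPerStrip
  tag(279, 4, 1, length(raw_data))    # StripByteCounts
  tag(282, 5, 1, off_xres)            # XResolution
  tag(283, 5, 1, off_yres)            # YResolution
  tag(296, 3, 1, 3)                   # ResolutionUnit: cm
  writeBin(0L, con, size = 4, endian = "little")  # next IFD
  invisible(path)
}

#' Tile windows covering a raster
#'
#' Row-major, non-overlapping, half-open windows `[x0,x1) x [y0,y1)` in
#' 0-based pixel coordinates (x = column, y = row), exactly covering the
#' raster; edge tiles are truncated.
#'
#' @param slide a [wsi], or anything with `$width_px`/`$height_px`.
#' @param tile_px tile side length in pixels (>= 1).
#' @return data.frame with columns x0, y0, x1, y1.
#' @export
iter_tiles <- function(slide, tile_px) {
  stopifnot(tile_px >= 1)
  w <- slide$width_px; h <- slide$height_px
  xs <- seq.int(0L, w - 1L, by = tile_px)
  ys <- seq.int(0L, h - 1L, by = tile_px)
  g <- expand.grid(x0 = xs, y0 = ys)[, c("x0", "y0")]
  g <- g[order(g$y0, g$x0), ]
  data.frame(x0 = g$x0, y0 = g$y0,
             x1 = pmin(g$x0 + tile_px, w), y1 = pmin(g$y0 + tile_px, h))
}

#' Write / read a boolean mask
#'
#' Masks round-trip losslessly through single-channel 8-bit PNG or TIFF:
#' `TRUE` maps to 255 and `FALSE` to 0.
#'
#' @param mask logical matrix.
#' @param path destination / source (`.png` or `.tif`/`.tiff`).
#' @return `write_mask`: `path` invisibly; `read_mask`: a logical matrix.
#' @export
write_mask <- function(mask, path) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("`mask` must be a logical matrix")
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(mask), nrow = nrow(mask))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(img, path, compression = "none")
  else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported mask format: .", ext)
  if (length(dim(img)) != 2L)
    stop("mask file must be single-channel: ", path)
  v <- round(img * 255)
  if (!all(v %in% c(0, 255)))
    stop("mask file has values other than {0, 255}: ", path)
  v == 255
}
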