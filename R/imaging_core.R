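# Core image containers: single-waveband images, band stacks, RGB images,
# reflectance maps, pixel masks and per-pixel index maps, plus raster I/O.
#
# Conventions: matrices are row-major images with the first row at the top of
# the picture; exported pixel coordinates are 0-based (x = column, y = row)
# with the origin at the top-left.

#' Construct a single-waveband image
#'
#' A band image is one 8-bit monochrome image taken under narrow-band
#' illumination, tagged with the peak wavelength and full width at half
#' maximum (FWHM) of the illuminating LED. Intensities are integers in
#' \[0, 255\] and serve as the reflectance proxy used by the anthocyanin
#' indices.
#'
#' @param intensities Integer matrix with values in \[0, 255\].
#' @param peak_nm Peak wavelength of the illumination band (nm), > 0.
#' @param fwhm_nm Full width at half maximum of the band (nm), > 0.
#' @param exposure_scale Dimensionless gain already applied at acquisition
#'   (default 1). Tracked so that ratio indices can refuse to mix bands with
#'   inconsistent gains.
#' @return An object of class `band_image`.
#' @export
band_image <- function(intensities, peak_nm, fwhm_nm, exposure_scale = 1) {
  if (!is.matrix(intensities)) stopf("intensities must be a matrix")
  v <- as.vector(intensities)
  if (anyNA(v)) stopf("intensities contain NA")
  if (any(v < 0 | v > 255)) stopf("intensities out of the 8-bit range [0, 255]")
  if (any(v != round(v))) stopf("intensities must be integers")
  if (!is.numeric(peak_nm) || length(peak_nm) != 1L || peak_nm <= 0)
    stopf("peak_nm must be a single positive number")
  if (!is.numeric(fwhm_nm) || length(fwhm_nm) != 1L || fwhm_nm <= 0)
    stopf("fwhm_nm must be a single positive number")
  if (!is.numeric(exposure_scale) || length(exposure_scale) != 1L ||
      exposure_scale <= 0)
    stopf("exposure_scale must be a single positive number")
  m <- intensities
  storage.mode(m) <- "integer"
  structure(
    list(intensities = m, peak_nm = as.numeric(peak_nm),
         fwhm_nm = as.numeric(fwhm_nm),
         exposure_scale = as.numeric(exposure_scale)),
    class = "band_image")
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("<band_image> %dx%d px, peak %g nm (FWHM %g nm), gain %g\n",
              nrow(x$intensities), ncol(x$intensities),
              x$peak_nm, x$fwhm_nm, x$exposure_scale))
  cat(sprintf("  intensity range: %d..%d\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.band_image <- function(x) dim(x$intensities)

#' Construct an aligned stack of band images
#'
#' @param bands Named list of [band_image()] objects; names are band roles
#'   (typically `green`, `red`, `nir`). All bands must share dimensions and
#'   role names must be unique.
#' @return An object of class `spectral_stack` with `bands`, `width`
#'   (columns) and `height` (rows).
#' @export
spectral_stack <- function(bands) {
  if (!is.list(bands) || length(bands) == 0L) stopf("bands must be a non-empty list")
  nms <- names(bands)
  if (is.null(nms) || any(!nzchar(nms))) stopf("every band needs a role name")
  if (anyDuplicated(nms)) stopf("band role names must be unique")
  for (nm in nms)
    if (!inherits(bands[[nm]], "band_image"))
      stopf("band '%s' is not a band_image", nm)
  d <- dim(bands[[1L]]$intensities)
  for (nm in nms)
    check_same_dim(bands[[nm]]$intensities, bands[[1L]]$intensities,
                   sprintf("bands '%s' and '%s'", nm, nms[1L]))
  structure(list(bands = bands, width = d[2L], height = d[1L]),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  cat(sprintf("<spectral_stack> %dx%d px, bands: %s\n", x$height, x$width,
              paste(sprintf("%s (%g nm)", names(x$bands),
                            vapply(x$bands, `[[`, 0, "peak_nm")),
                    collapse = ", ")))
  invisible(x)
}

#' Construct an 8-bit RGB image
#'
#' @param red,green,blue Integer matrices in \[0, 255\] with identical
#'   dimensions, or `red` may be an `height x width x 3` array (then `green`
#'   and `blue` are omitted).
#' @return An object of class `rgb_image` with elements `red`, `green`,
#'   `blue`.
#' @export
rgb_image <- function(red, green = NULL, blue = NULL) {
  if (is.array(red) && length(dim(red)) == 3L) {
    if (dim(red)[3L] != 3L)
      stopf("expected 3 channels, got %d", dim(red)[3L])
    arr <- red
    red <- arr[, , 1L]; green <- arr[, , 2L]; blue <- arr[, , 3L]
  }
  chans <- list(red = red, green = green, blue = blue)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch)) stopf("channel '%s' must be a matrix", nm)
    v <- as.vector(ch)
    if (anyNA(v) || any(v < 0 | v > 255) || any(v != round(v)))
      stopf("channel '%s' must hold integers in [0, 255]", nm)
    storage.mode(chans[[nm]]) <- "integer"
  }
  check_same_dim(chans$red, chans$green, "red and green channels")
  check_same_dim(chans$red, chans$blue, "red and blue channels")
  structure(chans, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %dx%d px\n", nrow(x$red), ncol(x$red)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$red)

#' Construct a reflectance map
#'
#' @param values Numeric matrix with values in \[0, 1\].
#' @return An object of class `reflectance_map`.
#' @export
reflectance_map <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (anyNA(values)) stopf("reflectance values contain NA")
  if (any(values < 0 | values > 1))
    stopf("reflectance values out of [0, 1]")
  structure(list(values = values), class = "reflectance_map")
}

#' @export
print.reflectance_map <- function(x, ...) {
  cat(sprintf("<reflectance_map> %dx%d px, range %.4f..%.4f\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.reflectance_map <- function(x) dim(x$values)

#' Convert 8-bit intensities to reflectance
#'
#' Pixel intensities are divided by 255 so that full scale maps to a
#' reflectance of 1. This presumes the band has been gray-card calibrated
#' (see [exposure_correction()]); the conversion itself is a fixed linear
#' rescaling.
#'
#' @param band A [band_image()].
#' @return A [reflectance_map()] with values in \[0, 1\].
#' @export
to_reflectance <- function(band) {
  if (!inherits(band, "band_image")) stopf("band must be a band_image")
  reflectance_map(band$intensities / 255)
}

#' Construct a pixel mask
#'
#' @param flags Logical matrix; `TRUE` marks plant pixels.
#' @return An object of class `pixel_mask` with `flags` and the count
#'   `n_true`.
#' @export
pixel_mask <- function(flags) {
  if (!is.matrix(flags) || !is.logical(flags))
    stopf("flags must be a logical matrix")
  if (anyNA(flags)) stopf("mask flags contain NA")
  structure(list(flags = flags, n_true = sum(flags)), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %dx%d px, %d flagged (%.1f%%)\n",
              nrow(x$flags), ncol(x$flags), x$n_true,
              100 * x$n_true / length(x$flags)))
  invisible(x)
}

#' @export
dim.pixel_mask <- function(x) dim(x$flags)

# Internal index-map constructor; enforces the bookkeeping invariant
# valid + undefined <= plant-mask pixels.
index_map <- function(name, values, valid, n_undefined, mask_n = NULL) {
  stopifnot(is.matrix(values), inherits(valid, "pixel_mask"))
  if (!is.null(mask_n) && valid$n_true + n_undefined > mask_n)
    stopf("index map bookkeeping broken: %d valid + %d undefined > %d masked",
          valid$n_true, n_undefined, mask_n)
  structure(list(name = name, values = values, valid = valid,
                 n_undefined = as.integer(n_undefined)),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  v <- x$values[x$valid$flags]
  cat(sprintf("<index_map> %s, %dx%d px, %d valid, %d undefined\n",
              x$name, nrow(x$values), ncol(x$values), x$valid$n_true,
              x$n_undefined))
  if (length(v))
    cat(sprintf("  value range: %.4f..%.4f, mean %.4f\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

#' @export
dim.index_map <- function(x) dim(x$values)

# ---- raster I/O -------------------------------------------------------------

read_raster <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stopf("cannot decode '%s': %s", path,
                                            conditionMessage(e)))
    depth <- attr(x, "info")$bit.depth %||% 8
  } else if (ext %in% c("tif", "tiff")) {
    x <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stopf("cannot decode '%s': %s", path,
                                            conditionMessage(e)))
    depth <- attr(x, "bits.per.sample") %||% 8
  } else {
    stopf("unsupported raster format '%s' (use PNG or TIFF)", ext)
  }
  if (any(depth != 8))
    stopf("'%s' has bit depth %s; only 8-bit images are accepted", path,
          paste(depth, collapse = "/"))
  x
}

#' Read a single-waveband image from PNG or TIFF
#'
#' Only 8-bit single-channel rasters are accepted; deeper bit depths are
#' rejected rather than silently rescaled so that ratio-of-intensity indices
#' never see a hidden scale change.
#'
#' @param path Path to an 8-bit grayscale PNG or TIFF file.
#' @param peak_nm,fwhm_nm Illumination band metadata attached to the image.
#' @return A [band_image()].
#' @export
read_band_image <- function(path, peak_nm, fwhm_nm) {
  x <- read_raster(path)
  if (length(dim(x)) == 3L)
    stopf("'%s' has %d channels; a band image must be single-channel",
          path, dim(x)[3L])
  band_image(matrix(as.integer(round_half_up(x * 255)), nrow(x), ncol(x)),
             peak_nm = peak_nm, fwhm_nm = fwhm_nm)
}

#' Write a band image as an 8-bit grayscale PNG or TIFF
#'
#' @param band A [band_image()].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_band_image <- function(band, path) {
  if (!inherits(band, "band_image")) stopf("band must be a band_image")
  g <- band$intensities / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(g, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(g, path, bits.per.sample = 8L)
  else stopf("unsupported raster format '%s' (use PNG or TIFF)", ext)
  invisible(path)
}

#' Read an 8-bit 3-channel color image
#'
#' @param path Path to an 8-bit RGB PNG or TIFF file.
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) != 3L)
    stopf("'%s' has 1 channel; an RGB image must have 3", path)
  if (dim(x)[3L] != 3L)
    stopf("'%s' has %d channels; an RGB image must have 3", path, dim(x)[3L])
  ints <- round_half_up(x * 255)
  rgb_image(matrix(as.integer(ints[, , 1L]), dim(x)[1L], dim(x)[2L]),
            matrix(as.integer(ints[, , 2L]), dim(x)[1L], dim(x)[2L]),
            matrix(as.integer(ints[, , 3L]), dim(x)[1L], dim(x)[2L]))
}

#' Write an RGB image as an 8-bit PNG or TIFF
#'
#' @param rgb An [rgb_image()].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(rgb, path) {
  if (!inherits(rgb, "rgb_image")) stopf("rgb must be an rgb_image")
  arr <- array(0, c(dim(rgb$red), 3L))
  arr[, , 1L] <- rgb$red / 255
  arr[, , 2L] <- rgb$green / 255
  arr[, , 3L] <- rgb$blue / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  else stopf("unsupported raster format '%s' (use PNG or TIFF)", ext)
  invisible(path)
}

#' Render an index map as a false-color raster with a CSV sidecar
#'
#' Valid plant pixels are colormapped (viridis) over `scale`; background and
#' undefined pixels are rendered black. The sidecar CSV lists one row per
#' valid pixel as `x,y,value` (0-based coordinates, origin top-left,
#' row-major order) and a leading comment line recording the index name,
#' the `mean +/- sd` annotation (3 decimals, matching [index_summary()]) and
#' the scale-bar range.
#'
#' @param map An index map as returned by the index functions.
#' @param path Output PNG path.
#' @param scale Length-2 numeric `(lo, hi)` for the color scale, or `NULL`
#'   to use the range of the valid values. Values outside the scale are
#'   clipped to its endpoints in the rendering (the CSV always holds the raw
#'   values).
#' @param csv_path Sidecar CSV path; defaults to `path` with a `.csv`
#'   extension.
#' @return Invisibly, a list with the written paths, the scale used and the
#'   annotation string.
#' @export
write_index_map <- function(map, path, scale = NULL,
                            csv_path = paste0(tools::file_path_sans_ext(path), ".csv")) {
  if (!inherits(map, "index_map")) stopf("map must be an index_map")
  flags <- map$valid$flags
  if (map$valid$n_true == 0L)
    stopf("index map '%s' has no valid pixels; nothing written", map$name)
  v <- map$values[flags]
  if (is.null(scale)) scale <- range(v)
  if (length(scale) != 2L || scale[1L] > scale[2L])
    stopf("scale must be (lo, hi) with lo <= hi")
  lo <- scale[1L]; hi <- scale[2L]
  span <- if (hi > lo) hi - lo else 1
  t01 <- pmin(pmax((map$values - lo) / span, 0), 1)
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, "viridis"))
  arr <- array(0, c(dim(map$values), 3L))
  cols <- ramp(t01[flags]) / 255
  for (k in 1:3) {
    plane <- matrix(0, nrow(map$values), ncol(map$values))
    plane[flags] <- cols[, k]
    arr[, , k] <- plane
  }
  png::writePNG(arr, path)

  idx <- which(flags, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])  # row-major
  idx <- idx[ord, , drop = FALSE]
  ann <- sprintf("%.3f +/- %.3f", mean(v), sqrt(mean((v - mean(v))^2)))
  con <- file(csv_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: mean +/- sd = %s; scale = [%g, %g]",
                     map$name, ann, lo, hi), con)
  writeLines("x,y,value", con)
  writeLines(sprintf("%d,%d,%.6f", idx[, 2L] - 1L, idx[, 1L] - 1L,
                     map$values[idx]), con)
  invisible(list(png = path, csv = csv_path, scale = c(lo, hi),
                 annotation = ann))
}

#' Read an index-map sidecar CSV
#'
#' @param path CSV written by [write_index_map()].
#' @return A data frame with columns `x`, `y`, `value`.
#' @export
read_index_csv <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  utils::read.csv(path, comment.char = "#")
}
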