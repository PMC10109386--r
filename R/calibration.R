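# Gray-card exposure calibration. A middle-gray card reflects 50% at all
# wavebands, so a correctly exposed 8-bit image of it should read 127 of 255.
# One multiplicative gain per band, computed from the measured card
# intensity, makes images taken under different LEDs directly comparable.
# The gain is applied digitally; sensor response is assumed linear, as a
# single-point gray correction implies.

#' Mean intensity of a gray-card region
#'
#' @param band A [band_image()] of the gray card.
#' @param region Numeric `c(x, y, width, height)` rectangle, 0-based `x`
#'   (column) and `y` (row), origin top-left; must lie inside the image and
#'   contain at least one pixel. `NULL` uses the whole image.
#' @return The arithmetic mean intensity of the region.
#' @export
measure_gray_region <- function(band, region = NULL) {
  if (!inherits(band, "band_image")) stopf("band must be a band_image")
  d <- dim(band$intensities)
  if (is.null(region)) region <- c(0, 0, d[2L], d[1L])
  if (length(region) != 4L || any(!is.finite(region)))
    stopf("region must be c(x, y, width, height)")
  x <- region[1L]; y <- region[2L]; w <- region[3L]; h <- region[4L]
  if (w < 1 || h < 1) stopf("region is empty")
  if (x < 0 || y < 0 || x + w > d[2L] || y + h > d[1L])
    stopf("region [%g,%g %gx%g] is out of bounds for a %dx%d image",
          x, y, w, h, d[1L], d[2L])
  mean(band$intensities[(y + 1):(y + h), (x + 1):(x + w)])
}

#' Exposure-correction factor from a gray-card measurement
#'
#' The factor is the ratio between the 8-bit middle-gray target 127 and the
#' measured card intensity; applying it as a gain brings the card to 127
#' (before integer quantization).
#'
#' @param measured_gray Mean gray-card intensity, in (0, 255\].
#' @param band_role Optional band role name recorded in the result.
#' @return An object of class `calibration_result` with `band_role`,
#'   `measured_gray`, `exposure_factor` and a logical `clipping_risk` flag
#'   (set when the factor could push full-range pixels past 255, i.e. when
#'   `measured_gray < 127`).
#' @export
exposure_correction <- function(measured_gray, band_role = NA_character_) {
  if (!is.numeric(measured_gray) || length(measured_gray) != 1L ||
      !is.finite(measured_gray) || measured_gray <= 0)
    stopf("measured_gray must be a single positive intensity (card too dark or saturated-dark?)")
  if (measured_gray > 255) stopf("measured_gray exceeds the 8-bit range")
  factor <- 127 / measured_gray
  structure(list(band_role = band_role,
                 measured_gray = as.numeric(measured_gray),
                 exposure_factor = factor,
                 clipping_risk = factor > 1),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: measured gray %.2f -> factor %.4f%s\n",
              if (is.na(x$band_role)) "(band)" else x$band_role,
              x$measured_gray, x$exposure_factor,
              if (x$clipping_risk) " [clipping risk]" else ""))
  invisible(x)
}

#' Apply a digital gain to a band image
#'
#' Intensities are multiplied by `factor`, rounded half-away-from-zero and
#' clipped to \[0, 255\]; the image's `exposure_scale` is multiplied by the
#' same factor and the number of clipped pixels is recorded.
#'
#' @param band A [band_image()].
#' @param factor Positive gain, typically the `exposure_factor` of an
#'   [exposure_correction()].
#' @return A [band_image()] with attribute `n_clipped` (count of pixels
#'   clipped at 255).
#' @export
apply_gain <- function(band, factor) {
  if (!inherits(band, "band_image")) stopf("band must be a band_image")
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stopf("factor must be a single positive number")
  raw <- round_half_up(band$intensities * factor)
  n_clipped <- sum(raw > 255)
  out <- band_image(matrix(as.integer(pmin(pmax(raw, 0), 255)),
                           nrow(band$intensities), ncol(band$intensities)),
                    peak_nm = band$peak_nm, fwhm_nm = band$fwhm_nm,
                    exposure_scale = band$exposure_scale * factor)
  attr(out, "n_clipped") <- as.integer(n_clipped)
  out
}

#' Write per-band calibration factors to a YAML file
#'
#' @param results A list of [exposure_correction()] results (named by band
#'   role, or carrying their own `band_role`).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(results, path) {
  if (inherits(results, "calibration_result")) results <- list(results)
  out <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (!inherits(r, "calibration_result"))
      stopf("element %d is not a calibration_result", i)
    role <- names(results)[i] %||% r$band_role
    if (is.null(role) || is.na(role) || !nzchar(role)) role <- r$band_role
    if (is.na(role)) stopf("element %d has no band role", i)
    out[[role]] <- list(measured_gray = r$measured_gray,
                        exposure_factor = r$exposure_factor,
                        clipping_risk = r$clipping_risk)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read per-band calibration factors from a YAML file
#'
#' @param path YAML written by [write_calibration()].
#' @return Named list of `calibration_result` objects.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(role) {
    r <- exposure_correction(raw[[role]]$measured_gray, band_role = role)
    r
  })
  names(out) <- names(raw)
  out
}
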