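# Per-pixel anthocyanin indices.
#
# All indices exploit the same optics: anthocyanins absorb strongly in the
# green (~500-550 nm) and hardly at all in the red, while red reflectance
# tracks chlorophyll. Higher anthocyanin therefore lowers green reflectance
# relative to red, and every index below increases with anthocyanin content.
#
#   NDAI = (I_red - I_green) / (I_red + I_green)          (intensity or reflectance)
#   NARI = (1/R_green - 1/R_red) / (1/R_green + 1/R_red)  (reflectance)
#   ARI  = 1/R_green - 1/R_red                            (reflectance)
#   mACI = R_nir / R_green                                (reflectance)
#   mARI = (1/R_green - 1/R_red) * R_nir                  (reflectance)
#   RGI  = I_red / I_green                                (intensity or reflectance)
#
# NDAI, NARI and RGI are ratios of same-scale quantities and are invariant
# to a common rescaling, so intensities may be used directly; ARI, mACI and
# mARI take reciprocals or cross-band ratios of reflectance and are computed
# on the /255 reflectance scale. NARI is algebraically identical to NDAI
# wherever both reflectances are strictly positive.
#
# Pixels where a formula is undefined (zero denominator or a reciprocal of
# zero) are marked undefined and counted in n_undefined, never given
# sentinel values.

# Extract numeric pixel values plus scale bookkeeping from a band image or
# reflectance map.
px_values <- function(x, arg = "input") {
  if (inherits(x, "band_image"))
    list(values = x$intensities + 0, scale = "intensity",
         exposure = x$exposure_scale)
  else if (inherits(x, "reflectance_map"))
    list(values = x$values, scale = "reflectance", exposure = 1)
  else stopf("%s must be a band_image or reflectance_map", arg)
}

resolve_mask <- function(mask, d) {
  if (is.null(mask)) return(pixel_mask(matrix(TRUE, d[1L], d[2L])))
  if (!inherits(mask, "pixel_mask")) stopf("mask must be a pixel_mask")
  if (!identical(dim(mask$flags), d))
    stopf("mask dimensions %s do not match image dimensions %s",
          paste(dim(mask$flags), collapse = "x"), paste(d, collapse = "x"))
  mask
}

# Shared assembly: given value matrix and an undefined predicate matrix,
# restrict to the plant mask and account for undefined pixels.
build_index_map <- function(name, values, undefined, mask) {
  und <- undefined & mask$flags
  validf <- mask$flags & !undefined
  values[!validf] <- NA_real_
  index_map(name, values, pixel_mask(validf), sum(und), mask_n = mask$n_true)
}

#' Normalized difference anthocyanin index (NDAI)
#'
#' `(red - green) / (red + green)` per plant pixel, bounded in \[-1, 1\].
#' Being a normalized ratio, NDAI is invariant to a common rescaling of both
#' bands, so either raw 8-bit intensities or reflectances can be supplied
#' (both inputs must be on the same scale).
#'
#' @param green,red [band_image()]s or [reflectance_map()]s on a common
#'   scale and pixel grid.
#' @param mask Optional [pixel_mask()] of plant pixels; `NULL` means all.
#' @return An index map (class `index_map`); pixels with `red + green = 0`
#'   are undefined.
#' @export
ndai <- function(green, red, mask = NULL) {
  g <- px_values(green, "green"); r <- px_values(red, "red")
  if (g$scale != r$scale)
    stopf("green (%s) and red (%s) are on different scales", g$scale, r$scale)
  check_same_dim(g$values, r$values, "green and red")
  mask <- resolve_mask(mask, dim(g$values))
  den <- r$values + g$values
  vals <- (r$values - g$values) / den
  build_index_map("NDAI", vals, den == 0, mask)
}

#' Normalized anthocyanin reflectance index (NARI)
#'
#' `(1/green - 1/red) / (1/green + 1/red)` on reflectance; algebraically
#' identical to [ndai()] wherever both reflectances are strictly positive.
#'
#' @param green_r,red_r [reflectance_map()]s on one pixel grid.
#' @param mask Optional [pixel_mask()].
#' @return An index map; pixels with zero reflectance in either band are
#'   undefined.
#' @export
nari <- function(green_r, red_r, mask = NULL) {
  g <- px_values(green_r, "green_r"); r <- px_values(red_r, "red_r")
  if (g$scale != "reflectance" || r$scale != "reflectance")
    stopf("NARI requires reflectance maps")
  check_same_dim(g$values, r$values, "green and red")
  mask <- resolve_mask(mask, dim(g$values))
  ig <- 1 / g$values; ir <- 1 / r$values
  vals <- (ig - ir) / (ig + ir)
  build_index_map("NARI", vals, g$values == 0 | r$values == 0, mask)
}

#' Anthocyanin reflectance index (ARI)
#'
#' `1/green - 1/red` on reflectance.
#'
#' @inheritParams nari
#' @return An index map; zero reflectance in either band makes the pixel
#'   undefined.
#' @export
ari <- function(green_r, red_r, mask = NULL) {
  g <- px_values(green_r, "green_r"); r <- px_values(red_r, "red_r")
  if (g$scale != "reflectance" || r$scale != "reflectance")
    stopf("ARI requires reflectance maps")
  check_same_dim(g$values, r$values, "green and red")
  mask <- resolve_mask(mask, dim(g$values))
  vals <- 1 / g$values - 1 / r$values
  build_index_map("ARI", vals, g$values == 0 | r$values == 0, mask)
}

#' Modified anthocyanin content index (mACI)
#'
#' `nir / green` on reflectance. Uses NIR rather than red, so it carries no
#' chlorophyll correction.
#'
#' @param nir_r,green_r [reflectance_map()]s on one pixel grid.
#' @param mask Optional [pixel_mask()].
#' @return An index map; zero green reflectance makes the pixel undefined.
#' @export
maci <- function(nir_r, green_r, mask = NULL) {
  n <- px_values(nir_r, "nir_r"); g <- px_values(green_r, "green_r")
  if (n$scale != "reflectance" || g$scale != "reflectance")
    stopf("mACI requires reflectance maps")
  check_same_dim(n$values, g$values, "nir and green")
  mask <- resolve_mask(mask, dim(g$values))
  vals <- n$values / g$values
  build_index_map("mACI", vals, g$values == 0, mask)
}

#' Modified anthocyanin reflectance index (mARI)
#'
#' `(1/green - 1/red) * nir` on reflectance; the NIR factor is meant to
#' compensate for leaf-structure scattering.
#'
#' @param green_r,red_r,nir_r [reflectance_map()]s on one pixel grid.
#' @param mask Optional [pixel_mask()].
#' @return An index map; zero green or red reflectance makes the pixel
#'   undefined (zero NIR gives a defined value of 0).
#' @export
mari <- function(green_r, red_r, nir_r, mask = NULL) {
  g <- px_values(green_r, "green_r"); r <- px_values(red_r, "red_r")
  n <- px_values(nir_r, "nir_r")
  if (g$scale != "reflectance" || r$scale != "reflectance" ||
      n$scale != "reflectance")
    stopf("mARI requires reflectance maps")
  check_same_dim(g$values, r$values, "green and red")
  check_same_dim(g$values, n$values, "green and nir")
  mask <- resolve_mask(mask, dim(g$values))
  vals <- (1 / g$values - 1 / r$values) * n$values
  build_index_map("mARI", vals, g$values == 0 | r$values == 0, mask)
}

#' Red:green ratio index (RGI)
#'
#' `red / green`; scale-invariant, so intensities or reflectances may be
#' supplied (both on the same scale).
#'
#' @param red,green [band_image()]s or [reflectance_map()]s on a common
#'   scale and pixel grid.
#' @param mask Optional [pixel_mask()].
#' @return An index map; zero green makes the pixel undefined.
#' @export
rgi <- function(red, green, mask = NULL) {
  r <- px_values(red, "red"); g <- px_values(green, "green")
  if (g$scale != r$scale)
    stopf("red (%s) and green (%s) are on different scales", r$scale, g$scale)
  check_same_dim(r$values, g$values, "red and green")
  mask <- resolve_mask(mask, dim(g$values))
  vals <- r$values / g$values
  build_index_map("RGI", vals, g$values == 0, mask)
}

#' Index definition lookup
#'
#' @param name One of `"NDAI"`, `"NARI"`, `"ARI"`, `"mACI"`, `"mARI"`,
#'   `"RGI"` (case-insensitive).
#' @return A list with `name`, `required_bands` and `input_scale`
#'   (`"any"` for the scale-invariant NDAI/NARI/RGI, `"reflectance"`
#'   otherwise).
#' @export
index_definition <- function(name) {
  defs <- list(
    NDAI = list(required_bands = c("green", "red"),        input_scale = "any"),
    NARI = list(required_bands = c("green", "red"),        input_scale = "reflectance"),
    ARI  = list(required_bands = c("green", "red"),        input_scale = "reflectance"),
    mACI = list(required_bands = c("nir", "green"),        input_scale = "reflectance"),
    mARI = list(required_bands = c("green", "red", "nir"), input_scale = "reflectance"),
    RGI  = list(required_bands = c("green", "red"),        input_scale = "any"))
  key <- names(defs)[match(toupper(name), toupper(names(defs)))]
  if (is.na(key))
    stopf("unknown index '%s' (expected one of %s)", name,
          paste(names(defs), collapse = ", "))
  c(list(name = key), defs[[key]])
}

#' List the available index names
#'
#' @return Character vector of index identifiers.
#' @export
index_names <- function() c("NDAI", "NARI", "ARI", "mACI", "mARI", "RGI")

#' Compute an index on a band stack or RGB image
#'
#' Dispatches to the individual index functions, converting intensities to
#' reflectance first when the index requires it. For RGB images the red and
#' green color channels substitute for the red and green band images
#' (NIR-requiring indices are unavailable). For a multispectral stack, all
#' bands an index uses must share the same `exposure_scale`; mixed gains
#' would silently distort ratio indices and are rejected.
#'
#' @param x A [spectral_stack()] or [rgb_image()].
#' @param definition An index name or the result of [index_definition()].
#' @param mask Optional [pixel_mask()] of plant pixels.
#' @return An index map.
#' @export
compute_index <- function(x, definition, mask = NULL) {
  if (is.character(definition)) definition <- index_definition(definition)
  need <- definition$required_bands
  refl <- definition$input_scale == "reflectance"

  if (inherits(x, "spectral_stack")) {
    missing_roles <- setdiff(need, names(x$bands))
    if (length(missing_roles))
      stopf("stack lacks required band role(s): %s",
            paste(missing_roles, collapse = ", "))
    gains <- vapply(x$bands[need], `[[`, 0, "exposure_scale")
    if (diff(range(gains)) > 1e-12)
      stopf("bands %s have differing exposure_scale; calibrate to a common gain first",
            paste(need, collapse = ", "))
    get_in <- function(role) {
      b <- x$bands[[role]]
      if (refl) to_reflectance(b) else b
    }
  } else if (inherits(x, "rgb_image")) {
    missing_roles <- setdiff(need, c("green", "red"))
    if (length(missing_roles))
      stopf("RGB images provide no %s channel required by %s",
            paste(missing_roles, collapse = ", "), definition$name)
    get_in <- function(role) {
      ch <- x[[if (role == "red") "red" else "green"]]
      b <- band_image(ch, peak_nm = if (role == "red") 596 else 521,
                      fwhm_nm = 100)
      if (refl) to_reflectance(b) else b
    }
  } else stopf("x must be a spectral_stack or rgb_image")

  switch(definition$name,
         NDAI = ndai(get_in("green"), get_in("red"), mask),
         NARI = nari(get_in("green"), get_in("red"), mask),
         ARI  = ari(get_in("green"), get_in("red"), mask),
         mACI = maci(get_in("nir"), get_in("green"), mask),
         mARI = mari(get_in("green"), get_in("red"), get_in("nir"), mask),
         RGI  = rgi(get_in("red"), get_in("green"), mask))
}
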