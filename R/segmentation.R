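# Plant/background segmentation.
#
# Multispectral stacks: intensity thresholding (fixed or Otsu) on one band
# followed by despeckling (removal of small connected components).
# RGB images: red:blue ratio thresholding (leaves absorb blue strongly, so
# plants have ratios well above 1, while a gray chamber floor sits near 1),
# refined by erosion and dilation.
#
# Otsu thresholding and the morphological operators are delegated to
# EBImage; connected components use an in-package 8-connected labeling
# (despeckling must not split diagonally-touching plant parts).

#' Segmentation parameters
#'
#' The source study reports the operations but not their numeric settings;
#' the defaults here (Otsu on the NIR band for stacks, red:blue threshold
#' 1.2, 3x3 kernel with one erosion and one dilation, minimum component
#' size 16 px) are a reasonable starting point and are all adjustable.
#'
#' @param method `"fixed_threshold"`, `"otsu"` or `"rb_ratio"`.
#' @param threshold Intensity cutoff for `fixed_threshold`, ratio cutoff for
#'   `rb_ratio`; ignored under `otsu`.
#' @param despeckle_min_px Minimum connected-component size kept (>= 0).
#' @param morph_kernel_px Side of the square structuring element; odd, >= 1.
#' @param erode_iter,dilate_iter Nonnegative iteration counts.
#' @param direction `"above"` (plant pixels brighter than the threshold,
#'   the default) or `"below"`.
#' @param band_role Band a stack is thresholded on (default `"nir"`, the
#'   band with the strongest plant/background contrast in vegetation).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(method = c("otsu", "fixed_threshold", "rb_ratio"),
                                threshold = 1.2, despeckle_min_px = 16,
                                morph_kernel_px = 3, erode_iter = 1,
                                dilate_iter = 1, direction = c("above", "below"),
                                band_role = "nir") {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (despeckle_min_px < 0) stopf("despeckle_min_px must be >= 0")
  if (morph_kernel_px < 1 || morph_kernel_px %% 2 != 1)
    stopf("morph_kernel_px must be odd and >= 1")
  if (erode_iter < 0 || dilate_iter < 0)
    stopf("iteration counts must be nonnegative")
  structure(list(method = method, threshold = threshold,
                 despeckle_min_px = as.integer(despeckle_min_px),
                 morph_kernel_px = as.integer(morph_kernel_px),
                 erode_iter = as.integer(erode_iter),
                 dilate_iter = as.integer(dilate_iter),
                 direction = direction, band_role = band_role),
            class = "segmentation_params")
}

#' @export
print.segmentation_params <- function(x, ...) {
  cat(sprintf(
    "<segmentation_params> %s (threshold %g, %s), despeckle >= %d px, %dx%d kernel, %d erode / %d dilate\n",
    x$method, x$threshold, x$direction, x$despeckle_min_px,
    x$morph_kernel_px, x$morph_kernel_px, x$erode_iter, x$dilate_iter))
  invisible(x)
}

#' Threshold a band image into a plant mask
#'
#' Under `fixed_threshold` pixels are compared against `params$threshold`
#' (strictly greater under `direction = "above"`, strictly less under
#' `"below"`). Under `otsu` the threshold maximizing the between-class
#' variance of the 256-bin intensity histogram is found first; the brighter
#' class is taken as plant under `"above"`.
#'
#' @param band A [band_image()].
#' @param params A [segmentation_params()] with method `fixed_threshold` or
#'   `otsu`.
#' @return A [pixel_mask()] with attribute `threshold` (the cutoff used).
#' @export
threshold_mask <- function(band, params) {
  if (!inherits(band, "band_image")) stopf("band must be a band_image")
  if (!inherits(params, "segmentation_params"))
    stopf("params must be segmentation_params")
  if (!params$method %in% c("fixed_threshold", "otsu"))
    stopf("threshold_mask requires method fixed_threshold or otsu")
  ints <- band$intensities
  if (params$method == "otsu") {
    if (min(ints) == max(ints))
      stopf("Otsu thresholding is undefined on a constant image")
    thr <- EBImage::otsu(ints / 255, range = c(0, 1), levels = 256) * 255
  } else {
    thr <- params$threshold
  }
  flags <- if (params$direction == "above") ints > thr else ints < thr
  out <- pixel_mask(flags)
  attr(out, "threshold") <- as.numeric(thr)
  out
}

# 8-connected component labeling by iterative minimum-label propagation.
# Returns an integer matrix; 0 = background, components numbered 1..k.
label_components <- function(flags) {
  h <- nrow(flags); w <- ncol(flags)
  lab <- matrix(0L, h, w)
  lab[flags] <- which(flags)  # linear index as provisional label
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- shift_mat(new, s[1L], s[2L])
      upd <- flags & sh > 0L & sh < new
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Remove small connected components from a mask
#'
#' Components are 8-connected; any component with fewer than `min_px` pixels
#' is removed, all other flags are left untouched. Idempotent.
#'
#' @param mask A [pixel_mask()].
#' @param min_px Minimum component size kept; 0 (or 1) is the identity.
#' @return A [pixel_mask()].
#' @export
despeckle <- function(mask, min_px) {
  if (!inherits(mask, "pixel_mask")) stopf("mask must be a pixel_mask")
  if (min_px < 0) stopf("min_px must be >= 0")
  if (min_px <= 1L || mask$n_true == 0L) return(mask)
  lab <- label_components(mask$flags)
  sizes <- tabulate(lab)
  keep <- sizes >= min_px
  flags <- mask$flags
  flags[flags] <- keep[lab[flags]]
  pixel_mask(flags)
}

#' Segment plants in an RGB image by the red:blue ratio
#'
#' Plant pixels absorb blue strongly, so `red / blue` exceeds 1 on plants
#' while a spectrally flat background stays near 1. The ratio is compared
#' against `params$threshold` (blue floored at 1 to guard the division) and
#' the raw mask is refined by [morph_refine()] with the same parameters.
#'
#' @param rgb An [rgb_image()].
#' @param params A [segmentation_params()] with `method = "rb_ratio"` and a
#'   positive threshold.
#' @return A [pixel_mask()].
#' @export
rb_ratio_mask <- function(rgb, params) {
  if (!inherits(rgb, "rgb_image")) stopf("rgb must be an rgb_image")
  if (!inherits(params, "segmentation_params"))
    stopf("params must be segmentation_params")
  if (params$method != "rb_ratio")
    stopf("rb_ratio_mask requires method rb_ratio")
  if (params$threshold <= 0) stopf("rb_ratio threshold must be > 0")
  ratio <- rgb$red / pmax(rgb$blue, 1L)
  morph_refine(pixel_mask(ratio > params$threshold), params)
}

as_plain_matrix <- function(x, h, w) matrix(as.numeric(x), h, w)

#' Refine a mask by erosion then dilation
#'
#' Applies `erode_iter` erosions followed by `dilate_iter` dilations with
#' one square structuring element of side `morph_kernel_px` (a morphological
#' opening when the counts are equal, which removes protrusions thinner than
#' the kernel while preserving the bulk shape).
#'
#' @param mask A [pixel_mask()].
#' @param params A [segmentation_params()] supplying the kernel and
#'   iteration counts.
#' @return A [pixel_mask()].
#' @export
morph_refine <- function(mask, params) {
  if (!inherits(mask, "pixel_mask")) stopf("mask must be a pixel_mask")
  if (!inherits(params, "segmentation_params"))
    stopf("params must be segmentation_params")
  if (params$erode_iter == 0L && params$dilate_iter == 0L) return(mask)
  h <- nrow(mask$flags); w <- ncol(mask$flags)
  kern <- EBImage::makeBrush(params$morph_kernel_px, shape = "box")
  m <- mask$flags * 1
  for (i in seq_len(params$erode_iter))
    m <- as_plain_matrix(EBImage::erode(m, kern), h, w)
  for (i in seq_len(params$dilate_iter))
    m <- as_plain_matrix(EBImage::dilate(m, kern), h, w)
  pixel_mask(m > 0.5)
}

#' Intersection-over-union of two masks
#'
#' @param a,b [pixel_mask()]s with matching dimensions.
#' @return `|a AND b| / |a OR b|` in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!inherits(a, "pixel_mask") || !inherits(b, "pixel_mask"))
    stopf("a and b must be pixel_masks")
  check_same_dim(a$flags, b$flags, "masks")
  un <- sum(a$flags | b$flags)
  if (un == 0L) return(1)
  sum(a$flags & b$flags) / un
}

#' Segment plant pixels with the default pipeline for the input type
#'
#' Multispectral stacks are thresholded on `params$band_role` (Otsu by
#' default) and despeckled; RGB images use red:blue ratio thresholding with
#' morphological refinement, then despeckling.
#'
#' @param x A [spectral_stack()] or [rgb_image()].
#' @param params A [segmentation_params()]; for stacks the method must be
#'   `fixed_threshold` or `otsu`, for RGB images it is coerced to
#'   `rb_ratio`.
#' @return A [pixel_mask()].
#' @export
segment_plant <- function(x, params = NULL) {
  if (inherits(x, "spectral_stack")) {
    if (is.null(params)) params <- segmentation_params(method = "otsu")
    role <- params$band_role
    if (!role %in% names(x$bands))
      stopf("stack lacks the thresholding band '%s'", role)
    m <- threshold_mask(x$bands[[role]], params)
    despeckle(m, params$despeckle_min_px)
  } else if (inherits(x, "rgb_image")) {
    if (is.null(params)) params <- segmentation_params(method = "rb_ratio")
    if (params$method != "rb_ratio") params$method <- "rb_ratio"
    m <- rb_ratio_mask(x, params)
    despeckle(m, params$despeckle_min_px)
  } else stopf("x must be a spectral_stack or rgb_image")
}

#' Write a mask as a 0/255 grayscale PNG
#'
#' @param mask A [pixel_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!inherits(mask, "pixel_mask")) stopf("mask must be a pixel_mask")
  png::writePNG(mask$flags * 1, path)
  invisible(path)
}

#' Read a mask from a 0/255 grayscale PNG
#'
#' @param path PNG written by [write_mask_png()].
#' @return A [pixel_mask()] (pixels > 127 are flagged).
#' @export
read_mask_png <- function(path) {
  b <- read_band_image(path, peak_nm = 550, fwhm_nm = 1)
  pixel_mask(b$intensities > 127L)
}
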