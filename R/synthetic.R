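# Synthetic leaf-disc and rosette scenes with known ground truth.
#
# The forward model maps per-object pigment levels to band reflectances in
# Beer-Lambert style (only the direction of the pigment effects is known
# from leaf optics; exponential attenuation is the simplest model with the
# right monotonicity and positivity):
#
#   R_green = Rg0 * exp(-anth_green * c - chl_green * chl)
#   R_red   = Rr0 * exp(-chl_red * chl)
#   R_nir   = Rn0                       (leaf structure, pigment-independent)
#
# Green reflectance falls with anthocyanin (c, ug/g FW) and chlorophyll
# (chl, arbitrary units); red falls with chlorophyll only; NIR is constant.
# Gaussian pixel noise (reflectance units) is added, values are clipped to
# [0, 1] and quantized to 8-bit. The background is spectrally flat.
#
# Default coefficients are chosen so that NDAI spans roughly -0.1 to 0.25
# over the default concentration range 108-1673 ug/g FW, matching the span
# such canopies exhibit.

#' Pigment-to-reflectance forward model
#'
#' @param Rg0,Rr0,Rn0 Base band reflectances in (0, 1\] at zero pigment.
#' @param anth_green Green-band absorption per unit anthocyanin
#'   (per ug/g FW).
#' @param chl_green,chl_red Chlorophyll absorption terms (green and red
#'   band, per chlorophyll unit).
#' @param noise_sd Gaussian pixel noise, reflectance units.
#' @param background_reflectance Flat background reflectance.
#' @param blue_anchor Plant reflectance anchored at 450 nm for RGB
#'   rendering; kept low because leaves absorb blue strongly, which is what
#'   gives the red:blue ratio its segmentation contrast.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(Rg0 = 0.34, Rr0 = 0.28, Rn0 = 0.55,
                          anth_green = 4.5e-4, chl_green = 0.10,
                          chl_red = 0.15, noise_sd = 0,
                          background_reflectance = 0.05,
                          blue_anchor = 0.06) {
  for (nm in c("Rg0", "Rr0", "Rn0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stopf("%s must be in (0, 1]", nm)
  }
  for (nm in c("anth_green", "chl_green", "chl_red", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stopf("%s must be >= 0", nm)
  }
  if (background_reflectance < 0 || background_reflectance > 1)
    stopf("background_reflectance must be in [0, 1]")
  if (blue_anchor < 0 || blue_anchor > 1)
    stopf("blue_anchor must be in [0, 1]")
  structure(list(Rg0 = Rg0, Rr0 = Rr0, Rn0 = Rn0, anth_green = anth_green,
                 chl_green = chl_green, chl_red = chl_red,
                 noise_sd = noise_sd,
                 background_reflectance = background_reflectance,
                 blue_anchor = blue_anchor),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "<forward_model> Rg0 %.2f Rr0 %.2f Rn0 %.2f | anth_green %.3g chl_green %.3g chl_red %.3g | noise sd %.3g, bg %.2f\n",
    x$Rg0, x$Rr0, x$Rn0, x$anth_green, x$chl_green, x$chl_red, x$noise_sd,
    x$background_reflectance))
  invisible(x)
}

#' Scene specification
#'
#' @param layout `"discs"` (grid of leaf discs) or `"rosette"` (overlapping
#'   leaves around the image center, canopy-style).
#' @param n_objects Number of discs or leaves, >= 1.
#' @param width,height Image size in pixels.
#' @param conc Per-object anthocyanin concentrations (ug/g FW), recycled to
#'   `n_objects`; `NULL` samples them uniformly from `conc_range`.
#' @param chl Per-object chlorophyll levels (arbitrary units); `NULL`
#'   samples uniformly from `chl_range`.
#' @param conc_range Sampling range for `conc`; the default 108-1673 ug/g
#'   FW is the span observed across cold-stressed red lettuce leaf discs.
#' @param chl_range Sampling range for `chl`.
#' @param disc_radius Object radius in pixels; `NULL` picks a radius that
#'   fits the layout. An explicit radius that pushes an object over the
#'   image border is an error.
#' @param seed RNG seed; every sampled quantity (pigments, noise) derives
#'   from it, so a spec renders reproducibly.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(layout = c("discs", "rosette"), n_objects = 1,
                       width = 64, height = 64, conc = NULL, chl = NULL,
                       conc_range = c(108, 1673), chl_range = c(0.8, 1.2),
                       disc_radius = NULL, seed = 1) {
  layout <- match.arg(layout)
  if (!is.numeric(n_objects) || n_objects < 1)
    stopf("n_objects must be >= 1")
  if (width < 8 || height < 8) stopf("image must be at least 8x8 px")
  if (!is.null(conc) && any(conc < 0)) stopf("conc must be nonnegative")
  if (conc_range[1L] > conc_range[2L] || conc_range[1L] < 0)
    stopf("invalid conc_range")
  structure(list(layout = layout, n_objects = as.integer(n_objects),
                 width = as.integer(width), height = as.integer(height),
                 conc = conc, chl = chl, conc_range = conc_range,
                 chl_range = chl_range, disc_radius = disc_radius,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %s, %d object(s), %dx%d px, seed %d\n",
              x$layout, x$n_objects, x$height, x$width, x$seed))
  invisible(x)
}

# Deterministic object placement; returns data.frame(cx, cy, r) in pixel
# units (columns = x, rows = y).
place_objects <- function(spec) {
  n <- spec$n_objects; w <- spec$width; h <- spec$height
  if (spec$layout == "discs") {
    g <- ceiling(sqrt(n))
    cw <- w / g; ch <- h / ceiling(n / g)
    r <- spec$disc_radius %||% (0.38 * min(cw, ch))
    ix <- (seq_len(n) - 1L) %% g
    iy <- (seq_len(n) - 1L) %/% g
    out <- data.frame(cx = (ix + 0.5) * cw, cy = (iy + 0.5) * ch, r = r)
  } else {
    cx0 <- (w + 1) / 2; cy0 <- (h + 1) / 2
    s <- min(w, h)
    if (n == 1L) {
      out <- data.frame(cx = cx0, cy = cy0,
                        r = spec$disc_radius %||% (0.3 * s))
    } else {
      d <- 0.22 * s
      r <- spec$disc_radius %||% (0.16 * s)
      ang <- 2 * pi * (seq_len(n) - 1L) / n
      out <- data.frame(cx = cx0 + d * cos(ang), cy = cy0 + d * sin(ang),
                        r = r)
    }
  }
  bad <- out$cx - out$r < 1 | out$cx + out$r > w |
         out$cy - out$r < 1 | out$cy + out$r > h
  if (any(bad))
    stopf("object(s) %s overlap the image border (radius %.1f px in a %dx%d image)",
          paste(which(bad), collapse = ", "), out$r[which(bad)[1L]], h, w)
  out
}

# Pigments for a spec: fixed values recycled, or sampled (call under
# with_seed so the draw order is shared by both renderers).
draw_pigments <- function(spec) {
  n <- spec$n_objects
  conc <- if (is.null(spec$conc)) stats::runif(n, spec$conc_range[1L], spec$conc_range[2L])
          else rep_len(spec$conc, n)
  chl <- if (is.null(spec$chl)) stats::runif(n, spec$chl_range[1L], spec$chl_range[2L])
         else rep_len(spec$chl, n)
  list(conc = conc, chl = chl)
}

# Object-id map (0 background; later objects overwrite earlier where
# leaves overlap) for a placement.
object_id_map <- function(spec, objs) {
  h <- spec$height; w <- spec$width
  id <- matrix(0L, h, w)
  col_x <- matrix(rep(seq_len(w), each = h), h, w)
  row_y <- matrix(rep(seq_len(h), times = w), h, w)
  for (k in seq_len(nrow(objs))) {
    inside <- (col_x - objs$cx[k])^2 + (row_y - objs$cy[k])^2 <= objs$r[k]^2
    id[inside] <- k
  }
  id
}

# Noiseless per-band reflectance maps for given pigments.
noiseless_maps <- function(spec, model, id, pig) {
  Rg_obj <- model$Rg0 * exp(-model$anth_green * pig$conc -
                              model$chl_green * pig$chl)
  Rr_obj <- model$Rr0 * exp(-model$chl_red * pig$chl)
  Rn_obj <- rep(model$Rn0, spec$n_objects)
  lut <- function(vals) {
    m <- matrix(model$background_reflectance, spec$height, spec$width)
    m[id > 0L] <- vals[id[id > 0L]]
    m
  }
  list(green = lut(Rg_obj), red = lut(Rr_obj), nir = lut(Rn_obj))
}

quantize_band <- function(refl, peak_nm, fwhm_nm) {
  band_image(matrix(as.integer(round_half_up(pmin(pmax(refl, 0), 1) * 255)),
                    nrow(refl), ncol(refl)),
             peak_nm = peak_nm, fwhm_nm = fwhm_nm)
}

#' Render a multispectral scene
#'
#' Renders green (516 nm), red (664 nm) and NIR (861 nm) band images of the
#' scene plus full ground truth. Rendering is deterministic for a given
#' `(spec, model)`: the same seed reproduces the stack bit for bit.
#'
#' @param spec A [scene_spec()].
#' @param model A [forward_model()].
#' @return An object of class `synthetic_scene`: a list with `stack`
#'   ([spectral_stack()]) and `truth` (true [pixel_mask()], per-object
#'   `conc`/`chl`, noiseless reflectance maps, the model, placement and
#'   seed).
#' @export
render_multispectral <- function(spec, model = forward_model()) {
  if (!inherits(spec, "scene_spec")) stopf("spec must be a scene_spec")
  if (!inherits(model, "forward_model")) stopf("model must be a forward_model")
  objs <- place_objects(spec)
  id <- object_id_map(spec, objs)
  res <- with_seed(spec$seed, {
    pig <- draw_pigments(spec)
    clean <- noiseless_maps(spec, model, id, pig)
    noisy <- lapply(clean, function(m) {
      if (model$noise_sd > 0)
        m <- m + stats::rnorm(length(m), sd = model$noise_sd)
      pmin(pmax(m, 0), 1)
    })
    list(pig = pig, clean = clean, noisy = noisy)
  })
  stack <- spectral_stack(list(
    green = quantize_band(res$noisy$green, 516, 40),
    red   = quantize_band(res$noisy$red, 664, 25),
    nir   = quantize_band(res$noisy$nir, 861, 28)))
  truth <- structure(list(
    mask = pixel_mask(id > 0L),
    object_id = id,
    conc = res$pig$conc, chl = res$pig$chl,
    noiseless = lapply(res$clean, reflectance_map),
    model = model, spec = spec, objects = objs, seed = spec$seed),
    class = "ground_truth")
  structure(list(stack = stack, truth = truth), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s, %d object(s), conc %s ug/g\n",
              x$truth$spec$layout, x$truth$spec$n_objects,
              paste(sprintf("%.0f", x$truth$conc), collapse = ", ")))
  print(if (!is.null(x$stack)) x$stack else x$rgb)
  invisible(x)
}

#' RGB camera model
#'
#' Per-channel spectral sensitivities are unit-peak Gaussians; the effective
#' response of a channel is its sensitivity times the illuminant spectrum,
#' renormalized to unit sum. Defaults place the blue/green/red peaks at
#' 450/521/596 nm with half-maximum spans of roughly 477-595 nm (green) and
#' 580-700 nm (red), emulating a consumer RGB sensor under warm-white LEDs:
#' channels overlap broadly and respond across the whole 400-700 nm range.
#'
#' @param peaks Named numeric, channel peak wavelengths (nm).
#' @param fwhm Named numeric, channel full widths at half maximum (nm).
#' @param wavelengths Wavelength grid (nm); must cover 400-700 nm for
#'   rendering.
#' @param illuminant Illuminant spectrum sampled on `wavelengths` (any
#'   positive scale), or `NULL` for a built-in warm-white LED shape (blue
#'   pump at ~452 nm plus a broad phosphor hump at ~600 nm).
#' @return An object of class `camera_model` with the sensitivity matrix
#'   (`channels x wavelengths`), the illuminant and the normalized
#'   effective response.
#' @export
camera_model <- function(peaks = c(blue = 450, green = 521, red = 596),
                         fwhm = c(blue = 70, green = 118, red = 120),
                         wavelengths = seq(400, 750, by = 2),
                         illuminant = NULL) {
  if (length(wavelengths) == 0L) stopf("wavelength grid is empty")
  chans <- c("blue", "green", "red")
  if (!all(chans %in% names(peaks)) || !all(chans %in% names(fwhm)))
    stopf("peaks and fwhm must name blue, green and red")
  if (any(fwhm[chans] <= 0)) stopf("fwhm must be positive")
  if (is.null(illuminant)) {
    illuminant <- 0.35 * exp(-0.5 * ((wavelengths - 452) / 18)^2) +
      exp(-0.5 * ((wavelengths - 600) / 55)^2)
  }
  if (length(illuminant) != length(wavelengths))
    stopf("illuminant must be sampled on the wavelength grid")
  if (any(illuminant < 0)) stopf("illuminant must be nonnegative")
  illuminant <- illuminant / max(illuminant)
  sens <- t(vapply(chans, function(ch) {
    s <- fwhm[[ch]] / (2 * sqrt(2 * log(2)))
    v <- exp(-0.5 * ((wavelengths - peaks[[ch]]) / s)^2)
    v / max(v)  # unit peak on the sampled grid
  }, numeric(length(wavelengths))))
  eff <- sweep(sens, 2L, illuminant, `*`)
  eff <- eff / rowSums(eff)
  structure(list(channels = chans, peaks = peaks[chans], fwhm = fwhm[chans],
                 wavelengths = wavelengths, illuminant = illuminant,
                 sensitivity = sens, effective = eff),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> peaks %s nm, grid %g..%g nm (%d points)\n",
              paste(sprintf("%s %g", x$channels, x$peaks), collapse = ", "),
              min(x$wavelengths), max(x$wavelengths), length(x$wavelengths)))
  invisible(x)
}

# Weights of the four reflectance anchors (450 blue, 516 green, 664 red,
# 861 nir) in each channel. A per-pixel reflectance curve is the linear
# interpolation of its anchor values (constant beyond the ends), so the
# channel integral reduces to a fixed 3x4 weight matrix.
channel_anchor_weights <- function(camera, anchors = c(450, 516, 664, 861)) {
  wl <- camera$wavelengths
  basis <- sapply(seq_along(anchors), function(j) {
    y <- numeric(length(anchors)); y[j] <- 1
    stats::approx(anchors, y, xout = wl, rule = 2)$y
  })
  camera$effective %*% basis
}

#' Render an RGB image of a scene
#'
#' Builds a coarse per-pixel spectral reflectance curve by interpolating
#' the scene's band reflectances (anchored at 450, 516, 664 and 861 nm; the
#' 450 nm plant anchor is the forward model's `blue_anchor`) and integrates
#' it against each channel's effective response. The broad channel overlap
#' of a consumer camera is thereby emulated. Pigment sampling matches
#' [render_multispectral()], so the same spec rendered both ways shares its
#' ground truth.
#'
#' @param spec A [scene_spec()].
#' @param model A [forward_model()].
#' @param camera A [camera_model()]; its grid must cover 400-700 nm.
#' @return An object of class `synthetic_scene` with `rgb` ([rgb_image()])
#'   and `truth`.
#' @export
render_rgb <- function(spec, model = forward_model(), camera = camera_model()) {
  if (!inherits(spec, "scene_spec")) stopf("spec must be a scene_spec")
  if (!inherits(model, "forward_model")) stopf("model must be a forward_model")
  if (!inherits(camera, "camera_model")) stopf("camera must be a camera_model")
  wl <- camera$wavelengths
  if (length(wl) == 0L) stopf("wavelength grid is empty")
  if (min(wl) > 400 || max(wl) < 700)
    stopf("wavelength grid must cover 400-700 nm (got %g-%g)", min(wl), max(wl))
  objs <- place_objects(spec)
  id <- object_id_map(spec, objs)
  W <- channel_anchor_weights(camera)
  res <- with_seed(spec$seed, {
    pig <- draw_pigments(spec)
    clean <- noiseless_maps(spec, model, id, pig)
    blue_map <- matrix(model$background_reflectance, spec$height, spec$width)
    blue_map[id > 0L] <- model$blue_anchor
    chan <- lapply(seq_len(3L), function(ci) {
      m <- W[ci, 1L] * blue_map + W[ci, 2L] * clean$green +
        W[ci, 3L] * clean$red + W[ci, 4L] * clean$nir
      if (model$noise_sd > 0)
        m <- m + stats::rnorm(length(m), sd = model$noise_sd)
      pmin(pmax(m, 0), 1)
    })
    list(pig = pig, clean = clean, chan = chan)
  })
  to_int <- function(m) matrix(as.integer(round_half_up(m * 255)),
                               spec$height, spec$width)
  rgb <- rgb_image(red = to_int(res$chan[[3L]]),
                   green = to_int(res$chan[[2L]]),
                   blue = to_int(res$chan[[1L]]))
  truth <- structure(list(
    mask = pixel_mask(id > 0L),
    object_id = id,
    conc = res$pig$conc, chl = res$pig$chl,
    noiseless = lapply(res$clean, reflectance_map),
    model = model, spec = spec, objects = objs, seed = spec$seed,
    camera = camera),
    class = "ground_truth")
  structure(list(rgb = rgb, truth = truth), class = "synthetic_scene")
}

#' Generate a synthetic index-evaluation table
#'
#' Renders `n_samples` single-disc multispectral scenes with pigments drawn
#' per sample, runs the full pipeline (segmentation, indices, object means)
#' on each, and returns the evaluation table consumed by
#' [compare_indices()].
#'
#' @param n_samples Number of discs (>= 5; the reference study used 50).
#' @param spec_template A [scene_spec()] supplying layout/size/ranges; its
#'   `n_objects` is forced to 1 and its seed is replaced per sample.
#' @param model A [forward_model()].
#' @param seed Master seed; per-sample seeds are drawn from it.
#' @param indices Index names to tabulate.
#' @param params [segmentation_params()] for plant extraction.
#' @return A data frame with columns `sample_id`, `concentration_ug_g` and
#'   one column of object-mean index values per requested index.
#' @export
make_evaluation_set <- function(n_samples = 50, spec_template = scene_spec(),
                                model = forward_model(), seed = 1,
                                indices = c("NDAI", "ARI", "mACI", "mARI", "RGI"),
                                params = segmentation_params()) {
  if (n_samples < 5) stopf("n_samples must be >= 5")
  sample_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_samples))
  rows <- lapply(seq_len(n_samples), function(i) {
    sp <- spec_template
    sp$n_objects <- 1L
    sp$seed <- sample_seeds[i]
    scene <- render_multispectral(sp, model)
    mask <- segment_plant(scene$stack, params)
    if (mask$n_true == 0L)
      stopf("sample %d segmented to an empty mask", i)
    vals <- vapply(indices, function(nm) {
      m <- compute_index(scene$stack, nm, mask)
      mean(m$values[m$valid$flags])
    }, 0)
    c(concentration_ug_g = scene$truth$conc[1L], vals)
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(sample_id = sprintf("disc_%03d", seq_len(n_samples)), out,
             check.names = FALSE)
}

#' Object-mean NDAI from multispectral and RGB renderings of shared scenes
#'
#' Renders each scene both as a multispectral stack (Otsu NIR segmentation)
#' and as an RGB image (red:blue ratio segmentation) and records the
#' object-mean NDAI from each pipeline, for cross-system consistency
#' checks.
#'
#' @param n_scenes Number of single-disc scenes.
#' @param spec_template A [scene_spec()] template (seed replaced per scene).
#' @param model A [forward_model()].
#' @param camera A [camera_model()].
#' @param seed Master seed.
#' @return Data frame with `sample_id`, `concentration_ug_g`, `ndai_ms`,
#'   `ndai_rgb`.
#' @export
cross_system_ndai <- function(n_scenes = 30, spec_template = scene_spec(),
                              model = forward_model(),
                              camera = camera_model(), seed = 1) {
  if (n_scenes < 2) stopf("n_scenes must be >= 2")
  sample_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_scenes))
  rows <- lapply(seq_len(n_scenes), function(i) {
    sp <- spec_template
    sp$n_objects <- 1L
    sp$seed <- sample_seeds[i]
    ms <- render_multispectral(sp, model)
    rgb <- render_rgb(sp, model, camera)
    m_ms <- segment_plant(ms$stack, segmentation_params(method = "otsu"))
    m_rgb <- segment_plant(rgb$rgb, segmentation_params(method = "rb_ratio"))
    if (m_ms$n_true == 0L || m_rgb$n_true == 0L)
      stopf("scene %d segmented to an empty mask", i)
    i_ms <- compute_index(ms$stack, "NDAI", m_ms)
    i_rgb <- compute_index(rgb$rgb, "NDAI", m_rgb)
    c(concentration_ug_g = ms$truth$conc[1L],
      ndai_ms = mean(i_ms$values[i_ms$valid$flags]),
      ndai_rgb = mean(i_rgb$values[i_rgb$valid$flags]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(sample_id = sprintf("scene_%03d", seq_len(n_scenes)), out)
}
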