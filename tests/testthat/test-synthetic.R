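# Synthetic scene generation and its ground truth.

test_that("rendering is deterministic under a fixed seed", {
  sp <- scene_spec(n_objects = 3, seed = 42)
  mdl <- forward_model(noise_sd = 0.02)
  a <- render_multispectral(sp, mdl)
  b <- render_multispectral(sp, mdl)
  for (role in c("green", "red", "nir"))
    expect_identical(a$stack$bands[[role]]$intensities,
                     b$stack$bands[[role]]$intensities)
  expect_identical(a$truth$conc, b$truth$conc)
  r1 <- render_rgb(sp, mdl)
  r2 <- render_rgb(sp, mdl)
  expect_identical(r1$rgb$red, r2$rgb$red)
  # and the two renderers share the pigment draw
  expect_identical(a$truth$conc, r1$truth$conc)
})

test_that("higher anthocyanin gives higher object-mean NDAI", {
  sp <- scene_spec(n_objects = 2, width = 80, height = 48,
                   conc = c(200, 1400), chl = 1, seed = 1)
  sc <- render_multispectral(sp)
  id <- sc$truth$object_id
  m <- compute_index(sc$stack, "NDAI", sc$truth$mask)
  m1 <- mean(m$values[id == 1L])
  m2 <- mean(m$values[id == 2L])
  expect_lt(m1, m2)
})

test_that("NDAI is flat across concentrations when the anthocyanin term is off", {
  mdl <- forward_model(anth_green = 0)
  sp <- scene_spec(n_objects = 2, width = 80, height = 48,
                   conc = c(150, 1600), chl = 1, seed = 2)
  sc <- render_multispectral(sp, mdl)
  id <- sc$truth$object_id
  m <- compute_index(sc$stack, "NDAI", sc$truth$mask)
  d <- abs(mean(m$values[id == 1L]) - mean(m$values[id == 2L]))
  expect_lt(d, 2 / 127)  # quantization-level agreement
})

test_that("noiseless reflectances survive 8-bit quantization within 1/510", {
  sp <- scene_spec(n_objects = 2, seed = 3)
  sc <- render_multispectral(sp)
  for (role in c("green", "red", "nir")) {
    back <- sc$stack$bands[[role]]$intensities / 255
    expect_lte(max(abs(back - sc$truth$noiseless[[role]]$values)), 1 / 510)
  }
})

test_that("objects pushed over the image border are an error", {
  expect_error(render_multispectral(scene_spec(disc_radius = 40, seed = 1)),
               "border")
})

test_that("rosette layouts render a multi-leaf canopy", {
  sp <- scene_spec(layout = "rosette", n_objects = 6, width = 96, height = 96,
                   seed = 4)
  sc <- render_multispectral(sp)
  expect_length(sc$truth$conc, 6)
  single <- render_multispectral(scene_spec(layout = "rosette", width = 96,
                                            height = 96, seed = 4))
  expect_gt(sc$truth$mask$n_true, single$truth$mask$n_true)
})

test_that("a spectrally flat scene renders gray under a flat illuminant", {
  mdl <- forward_model(Rg0 = 0.4, Rr0 = 0.4, Rn0 = 0.4, anth_green = 0,
                       chl_green = 0, chl_red = 0, blue_anchor = 0.4,
                       background_reflectance = 0.4)
  cam <- camera_model(illuminant = rep(1, length(seq(400, 750, by = 2))))
  sc <- render_rgb(scene_spec(seed = 5), mdl, cam)
  expect_lte(max(abs(sc$rgb$red - sc$rgb$green)), 1)
  expect_lte(max(abs(sc$rgb$red - sc$rgb$blue)), 1)
})

test_that("RGB and multispectral NDAI rank objects consistently", {
  cs <- cross_system_ndai(n_scenes = 12, model = forward_model(noise_sd = 0.01),
                          seed = 21)
  expect_gte(cor(cs$ndai_ms, cs$ndai_rgb, method = "spearman"), 0.9)
})

test_that("narrowing the camera channels onto the band peaks recovers multispectral NDAI", {
  sp <- scene_spec(seed = 6)
  ms <- render_multispectral(sp)
  narrow <- camera_model(peaks = c(blue = 450, green = 516, red = 664),
                         fwhm = c(blue = 4, green = 4, red = 4))
  rg <- render_rgb(sp, camera = narrow)
  mask <- ms$truth$mask
  i_ms <- compute_index(ms$stack, "NDAI", mask)
  i_rgb <- compute_index(rg$rgb, "NDAI", mask)
  d <- abs(mean(i_ms$values[i_ms$valid$flags]) -
             mean(i_rgb$values[i_rgb$valid$flags]))
  expect_lt(d, 0.02)
})

test_that("chlorophyll variation disturbs mACI more than NDAI", {
  # strong chlorophyll variability: the red band lets NDAI cancel most of
  # it; mACI (green/NIR only) cannot. Compare the chlorophyll-induced
  # spread at fixed anthocyanin against the anthocyanin-induced span at
  # fixed chlorophyll (nuisance:signal ratio).
  mdl <- forward_model(chl_green = 0.6, chl_red = 0.65)
  obj_means <- function(conc, chl, i) {
    sc <- render_multispectral(scene_spec(conc = conc, chl = chl,
                                          seed = 100 + i), mdl)
    mask <- sc$truth$mask
    c(ndai = mean(compute_index(sc$stack, "NDAI", mask)$values[mask$flags]),
      maci = mean(compute_index(sc$stack, "mACI", mask)$values[mask$flags]))
  }
  signal <- sapply(1:2, function(i) obj_means(c(108, 1673)[i], 1, i))
  chls <- seq(0.5, 1.5, length.out = 8)
  nuisance <- sapply(seq_along(chls), function(i) obj_means(800, chls[i], 10 + i))
  ratio <- function(k) (max(nuisance[k, ]) - min(nuisance[k, ])) /
    abs(signal[k, 2] - signal[k, 1])
  expect_lt(ratio("ndai"), ratio("maci"))
  # and on a mixed set, NDAI tracks anthocyanin rank better than mACI
  tab <- make_evaluation_set(n_samples = 30,
                             spec_template = scene_spec(chl_range = c(0.5, 1.5)),
                             model = mdl, seed = 7)
  s_ndai <- cor(tab$concentration_ug_g, tab$NDAI, method = "spearman")
  s_maci <- cor(tab$concentration_ug_g, tab$mACI, method = "spearman")
  expect_gt(s_ndai, s_maci)
})

test_that("evaluation sets are reproducible and monotone in concentration", {
  t1 <- make_evaluation_set(n_samples = 12, seed = 9)
  t2 <- make_evaluation_set(n_samples = 12, seed = 9)
  expect_identical(t1, t2)
  expect_gte(cor(t1$concentration_ug_g, t1$NDAI, method = "spearman"), 0.95)
  expect_error(make_evaluation_set(n_samples = 3), ">= 5")
})

test_that("camera models validate their inputs", {
  expect_error(camera_model(wavelengths = numeric(0)), "empty")
  expect_error(render_rgb(scene_spec(seed = 1),
                          camera = camera_model(wavelengths = seq(500, 750, 5))),
               "400-700")
  cam <- camera_model()
  expect_true(all(cam$sensitivity >= 0))
  expect_equal(unname(apply(cam$sensitivity, 1, max)), rep(1, 3))
  expect_equal(unname(rowSums(cam$effective)), rep(1, 3), tolerance = 1e-12)
})
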