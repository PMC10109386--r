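# Per-pixel index computation.

test_that("NDAI matches its defining ratio on boundary and interior cases", {
  m <- ndai(bimg(c(100, 0, 50, 60)), bimg(c(100, 50, 0, 20), peak = 664))
  expect_equal(as.vector(m$values), c(0, 1, -1, -0.5))
  expect_identical(m$n_undefined, 0L)
  z <- ndai(bimg(0), bimg(0, peak = 664))
  expect_identical(z$n_undefined, 1L)
  expect_identical(z$valid$n_true, 0L)
  expect_error(ndai(bimg(c(1, 2)), bimg(1, peak = 664)), "mismatched")
})

test_that("NDAI is bounded, antisymmetric and scale-invariant", {
  set.seed(7)
  g <- matrix(runif(256), 16, 16)
  r <- matrix(runif(256), 16, 16)
  a <- ndai(reflectance_map(g), reflectance_map(r))
  expect_true(all(abs(a$values[a$valid$flags]) <= 1))
  b <- ndai(reflectance_map(r), reflectance_map(g))
  expect_equal(a$values, -b$values)
  k <- 0.37
  ks <- ndai(reflectance_map(k * g), reflectance_map(k * r))
  expect_equal(a$values, ks$values, tolerance = 1e-12)
})

test_that("NARI evaluates its reciprocal form and is identical to NDAI", {
  # both the reciprocal form and the simplified difference form, by hand
  g <- 0.2; r <- 0.5
  recip <- (1 / g - 1 / r) / (1 / g + 1 / r)
  expect_equal(recip, 3 / 7)
  m <- nari(rmap(g), rmap(r))
  expect_equal(m$values[1, 1], 3 / 7)
  expect_equal(nari(rmap(0.4), rmap(0.4))$values[1, 1], 0)
  set.seed(11)
  gm <- matrix(runif(400, 0.01, 1), 20, 20)
  rm_ <- matrix(runif(400, 0.01, 1), 20, 20)
  dn <- ndai(reflectance_map(gm), reflectance_map(rm_))
  na <- nari(reflectance_map(gm), reflectance_map(rm_))
  expect_lt(max(abs(dn$values - na$values)), 1e-12)
})

test_that("ARI is the reciprocal difference with zero-reflectance pixels undefined", {
  expect_equal(ari(rmap(0.5), rmap(0.5))$values[1, 1], 0)
  expect_equal(ari(rmap(0.2), rmap(0.5))$values[1, 1], 3)
  m <- ari(rmap(c(0, 0.2)), rmap(c(0.5, 0.5)))
  expect_identical(m$n_undefined, 1L)
  expect_true(is.na(m$values[1, 1]))
})

test_that("mACI is the NIR:green ratio", {
  expect_equal(maci(rmap(0.8), rmap(0.2))$values[1, 1], 4)
  expect_equal(maci(rmap(0.33), rmap(0.33))$values[1, 1], 1)
  expect_identical(maci(rmap(0.8), rmap(0))$n_undefined, 1L)
})

test_that("mARI couples the reciprocal difference with NIR", {
  expect_equal(mari(rmap(0.2), rmap(0.5), rmap(0.8))$values[1, 1], 2.4)
  expect_equal(mari(rmap(0.3), rmap(0.3), rmap(0.9))$values[1, 1], 0)
  m0 <- mari(rmap(0.2), rmap(0.5), rmap(0))
  expect_equal(m0$values[1, 1], 0)  # zero NIR is defined
  expect_identical(m0$n_undefined, 0L)
})

test_that("RGI is the red:green ratio and cancels a common scale", {
  expect_equal(rgi(rmap(0.5), rmap(0.25))$values[1, 1], 2)
  expect_equal(rgi(rmap(0.4), rmap(0.4))$values[1, 1], 1)
  ints <- rgi(bimg(150, peak = 664), bimg(75))
  refl <- rgi(rmap(150 / 255), rmap(75 / 255))
  expect_equal(ints$values[1, 1], 2)
  expect_equal(refl$values[1, 1], 2)
  expect_identical(rgi(rmap(0.4), rmap(0))$n_undefined, 1L)
})

test_that("every vectorized index equals the scalar per-pixel oracle exactly", {
  set.seed(19)
  g <- matrix(sample(0:255, 1024, TRUE), 32, 32) / 255
  r <- matrix(sample(0:255, 1024, TRUE), 32, 32) / 255
  n <- matrix(sample(0:255, 1024, TRUE), 32, 32) / 255
  flags <- matrix(sample(c(TRUE, FALSE), 1024, TRUE, prob = c(0.8, 0.2)), 32, 32)
  mk <- pixel_mask(flags)
  got <- list(
    NDAI = ndai(reflectance_map(g), reflectance_map(r), mk),
    NARI = nari(reflectance_map(g), reflectance_map(r), mk),
    ARI = ari(reflectance_map(g), reflectance_map(r), mk),
    mACI = maci(reflectance_map(n), reflectance_map(g), mk),
    mARI = mari(reflectance_map(g), reflectance_map(r), reflectance_map(n), mk),
    RGI = rgi(reflectance_map(r), reflectance_map(g), mk))
  for (nm in names(got)) {
    expect_identical(got[[nm]]$values,
                     oracle_index(nm, g = g, r = r, n = n, mask = flags),
                     label = nm)
  }
})

test_that("indices increase as green reflectance decreases at fixed red", {
  greens <- seq(0.4, 0.05, by = -0.05)
  red <- 0.3; nir <- 0.6
  vals <- sapply(greens, function(g) c(
    ndai(rmap(g), rmap(red))$values[1, 1],
    ari(rmap(g), rmap(red))$values[1, 1],
    mari(rmap(g), rmap(red), rmap(nir))$values[1, 1],
    rgi(rmap(red), rmap(g))$values[1, 1]))
  for (k in 1:4) expect_true(all(diff(vals[k, ]) > 0))
})

test_that("compute_index dispatches, converts scale and checks bands", {
  g <- bimg(matrix(c(60L, 100L), 2, 4), h = 2, w = 4)
  r <- bimg(matrix(c(90L, 50L), 2, 4), h = 2, w = 4, peak = 664, fwhm = 25)
  n <- bimg(matrix(150L, 2, 4), h = 2, w = 4, peak = 861, fwhm = 28)
  stack <- spectral_stack(list(green = g, red = r, nir = n))
  m <- compute_index(stack, "NDAI")
  expect_equal(m$values, ndai(g, r)$values)
  # reflectance conversion happens for reflectance-scale indices
  m2 <- compute_index(stack, "ARI")
  expect_equal(m2$values, ari(to_reflectance(g), to_reflectance(r))$values)
  expect_error(compute_index(spectral_stack(list(green = g)), "ARI"), "red")
  expect_error(compute_index(stack, "XYZ"), "unknown index")
})

test_that("NDAI on a stack is identical on intensities and reflectances", {
  set.seed(23)
  g <- matrix(sample(1:255, 64, TRUE), 8, 8)
  r <- matrix(sample(1:255, 64, TRUE), 8, 8)
  ints <- ndai(bimg(g, h = 8, w = 8), bimg(r, h = 8, w = 8, peak = 664))
  refl <- ndai(reflectance_map(g / 255), reflectance_map(r / 255))
  expect_equal(ints$values, refl$values, tolerance = 1e-14)
})

test_that("NDAI on an RGB image uses the red and green channels", {
  rgb <- rgb_image(matrix(120L, 4, 4), matrix(80L, 4, 4), matrix(10L, 4, 4))
  m <- compute_index(rgb, "NDAI")
  expect_equal(m$values[1, 1], (120 - 80) / (120 + 80))
  expect_error(compute_index(rgb, "mARI"), "nir")
})

test_that("mixed exposure gains across bands are rejected for ratio indices", {
  g <- bimg(100, peak = 516)
  r <- band_image(matrix(100L, 1, 1), 664, 25, exposure_scale = 1.3)
  stack <- spectral_stack(list(green = g, red = r))
  expect_error(compute_index(stack, "NDAI"), "exposure_scale")
})
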