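# Index summaries and regression-based evaluation.

# Helper: an index map with prescribed values via NDAI on crafted inputs.
map_with_values <- function(vals) {
  # (r - g)/(r + g) = v with g + r = 1  =>  r = (1 + v)/2
  v <- matrix(vals, 1, length(vals))
  r <- (1 + v) / 2
  g <- 1 - r
  ndai(reflectance_map(g), reflectance_map(r))
}

test_that("index summaries report population statistics over valid pixels", {
  s <- index_summary(map_with_values(rep(0.1, 5)))
  expect_equal(s$mean, 0.1)
  expect_equal(s$sd, 0)
  expect_equal(s$cv, 0)
  s2 <- index_summary(map_with_values(c(0, 0.2)))
  expect_equal(s2$mean, 0.1)
  expect_equal(s2$sd, 0.1)  # population (n) denominator
  expect_equal(s2$cv, 1)
  set.seed(31)
  vals <- runif(200, -0.5, 0.5)
  s3 <- index_summary(map_with_values(vals))
  expect_equal(s3$mean, sum(vals) / 200, tolerance = 1e-12)
  expect_equal(s3$sd, sqrt(sum((vals - mean(vals))^2) / 200), tolerance = 1e-12)
  expect_equal(s3$min, min(vals))
  expect_equal(s3$max, max(vals))
})

test_that("histograms span the theoretical range for NDAI and sum to n_valid", {
  s <- index_summary(map_with_values(c(-0.9, 0, 0.9)), bins = 10)
  expect_equal(s$histogram$breaks[1], -1)
  expect_equal(s$histogram$breaks[11], 1)
  expect_equal(sum(s$histogram$counts), 3)
  g <- reflectance_map(matrix(0, 2, 2))
  expect_error(index_summary(ndai(g, g)), "no valid pixels")
})

test_that("summaries ignore background pixels and pixel order", {
  set.seed(8)
  vals <- matrix(runif(36, 0.1, 0.9), 6, 6)
  r <- (1 + vals) / 2; g <- 1 - r
  flags <- matrix(FALSE, 6, 6); flags[2:5, 2:5] <- TRUE
  m1 <- ndai(reflectance_map(g), reflectance_map(r), pixel_mask(flags))
  # perturb background wildly; summary must not change
  g2 <- g; r2 <- r
  g2[!flags] <- 0.99; r2[!flags] <- 0.01
  m2 <- ndai(reflectance_map(g2), reflectance_map(r2), pixel_mask(flags))
  expect_equal(index_summary(m1)$mean, index_summary(m2)$mean)
  expect_equal(index_summary(m1)$sd, index_summary(m2)$sd)
})

test_that("noiseless linear data fit exactly", {
  x <- c(100, 300, 500, 900, 1300, 1600)
  y <- 2 + 3e-4 * x
  fit <- fit_index_model(x, y, "linear")
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$rmse, 1e-12)
  expect_equal(unname(coef(fit)), c(2, 3e-4), tolerance = 1e-10)
})

test_that("quadratic coefficients are recovered against the normal-equations oracle", {
  x <- c(108, 300, 520, 800, 1100, 1400, 1673)
  beta <- c(-0.05, 3e-4, -8e-8)
  y <- beta[1] + beta[2] * x + beta[3] * x^2
  fit <- fit_index_model(x, y, "quadratic")
  expect_equal(unname(coef(fit)), oracle_polyfit(x, y, 2), tolerance = 1e-9)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-9)
})

test_that("AIC follows the least-squares formula on a fixed 6-point fixture", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0.9, 2.1, 2.9, 4.2, 5.1, 5.8)
  fit <- fit_index_model(x, y, "linear")
  # hand-computed: residuals from the closed-form slope/intercept
  b <- oracle_polyfit(x, y, 1)
  rss <- sum((y - b[1] - b[2] * x)^2)
  expect_equal(fit$aic, 6 * log(rss / 6) + 2 * 3, tolerance = 1e-9)
  expect_equal(fit$rmse, sqrt(rss / 6), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1 - rss / sum((y - mean(y))^2), tolerance = 1e-12)
  # overall F-test p-value
  sm <- summary(stats::lm(y ~ x))
  f <- sm$fstatistic
  expect_equal(fit$p_value, unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)))
})

test_that("degenerate designs are rejected", {
  expect_error(fit_index_model(rep(5, 6), 1:6, "linear"), "constant predictor")
  expect_error(fit_index_model(1:6, rep(2, 6), "linear"), "zero-variance")
  expect_error(fit_index_model(1:3, c(1, 2, 3.1), "quadratic"), "at least 4")
})

test_that("the quadratic fit never has lower R-squared than the nested linear fit", {
  for (s in 1:5) {
    set.seed(s)
    x <- runif(12, 100, 1600)
    y <- 0.1 + 2e-4 * x + rnorm(12, sd = 0.02)
    lin <- fit_index_model(x, y, "linear")
    quad <- fit_index_model(x, y, "quadratic")
    expect_gte(quad$r_squared, lin$r_squared - 1e-12)
  }
})

test_that("model selection compares AIC and breaks ties toward linear", {
  x <- seq(100, 1600, length.out = 20)
  curved <- 0.2 - 4e-4 * x + 5e-7 * x^2
  expect_equal(select_model(x, curved)$model, "quadratic")
  straight <- 0.01 + 1.5e-4 * x
  expect_equal(select_model(x, straight)$model, "linear")
  expect_warning(fit3 <- select_model(c(1, 2, 3), c(1, 2.1, 2.9)), "quadratic")
  expect_equal(fit3$model, "linear")
  expect_true(fit3$quadratic_infeasible)
})

test_that("compare_indices ranks a signal index above pure noise by AIC", {
  set.seed(13)
  conc <- runif(30, 108, 1673)
  tab <- data.frame(sample_id = sprintf("s%02d", 1:30),
                    concentration_ug_g = conc,
                    signal = 0.01 + 2e-4 * conc + rnorm(30, sd = 0.005),
                    noise = rnorm(30, sd = 0.05))
  out <- compare_indices(tab)
  expect_equal(out$Index[1], "signal")
  expect_gt(out$R2[out$Index == "signal"], out$R2[out$Index == "noise"])
  # single index column -> one row
  expect_equal(nrow(compare_indices(tab[, c("concentration_ug_g", "signal")])), 1)
  # permutation invariance
  out2 <- compare_indices(tab[sample(30), ])
  expect_equal(out, out2, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(compare_indices(tab[0, ]), "non-empty")
})

test_that("noise inflates RMSE and AIC of the evaluation fit", {
  set.seed(17)
  conc <- runif(25, 108, 1673)
  clean <- 0.01 + 2e-4 * conc
  noisy <- clean + rnorm(25, sd = 0.03)
  f_clean <- fit_index_model(conc, clean + rnorm(25, sd = 1e-4), "linear")
  f_noisy <- fit_index_model(conc, noisy, "linear")
  expect_lt(f_clean$rmse, f_noisy$rmse)
  expect_lt(f_clean$aic, f_noisy$aic)
})

test_that("concentration prediction inverts the calibration curve", {
  x <- seq(1, 5, length.out = 8)
  y <- 2 + 3 * x
  fit <- fit_index_model(x, y, "linear")
  expect_equal(predict_concentration(fit, 8), 2, tolerance = 1e-6)
  # round trip over the calibration range
  for (cc in c(1.2, 2.5, 4.9))
    expect_equal(predict_concentration(fit, predict(fit, cc)), cc,
                 tolerance = 1e-6)
  expect_error(predict_concentration(fit, 4.9), "outside the fitted range")
  # a quadratic that turns around inside the range is refused
  xq <- seq(0, 10, length.out = 12)
  yq <- (xq - 5)^2 + rnorm(12, sd = 1e-6)
  fq <- fit_index_model(xq, yq, "quadratic")
  expect_error(predict_concentration(fq, 5), "non-monotone")
})
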