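# Object-level index statistics and regression-based index evaluation.
#
# Evaluation regresses index on measured anthocyanin concentration
# (index ~ f(concentration), matching how such calibrations are plotted),
# fitting linear and quadratic ordinary least squares and comparing by AIC.
# Conventions, stated once and used throughout:
#   R2   = 1 - RSS/TSS
#   RMSE = sqrt(RSS / n)                    (n denominator, index units)
#   AIC  = n * log(RSS / n) + 2k            (least-squares form; k counts the
#                                            regression coefficients plus the
#                                            error variance)
#   p    = overall F-test of the fit
# The standard deviation of pixel summaries is the population (n) form.

#' Summary statistics of an index map over plant pixels
#'
#' @param map An index map (see [compute_index()]).
#' @param bins Number of histogram bins (default 50).
#' @param range Histogram range `(lo, hi)`; `NULL` uses the theoretical
#'   range for bounded indices (NDAI/NARI: \[-1, 1\]) and the data range
#'   otherwise.
#' @return An object of class `index_summary` with `mean`, `sd` (population
#'   form), `cv` (`sd/mean`, `NA` when the mean is 0), `min`, `max`,
#'   `n_valid`, `n_undefined`, and `histogram` (`breaks`, `counts`; counts
#'   sum to `n_valid`).
#' @export
index_summary <- function(map, bins = 50, range = NULL) {
  if (!inherits(map, "index_map")) stopf("map must be an index_map")
  v <- map$values[map$valid$flags]
  if (length(v) == 0L) stopf("index map '%s' has no valid pixels", map$name)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (is.null(range)) {
    range <- if (map$name %in% c("NDAI", "NARI")) c(-1, 1) else range(v)
  }
  if (range[1L] == range[2L]) range <- range + c(-0.5, 0.5)
  breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  # clip so every valid pixel lands in a bin even under a caller-set range
  vc <- pmin(pmax(v, range[1L]), range[2L])
  counts <- graphics::hist(vc, breaks = breaks, plot = FALSE)$counts
  structure(list(name = map$name, mean = m, sd = s,
                 cv = if (m != 0) s / m else NA_real_,
                 min = min(v), max = max(v),
                 n_valid = length(v), n_undefined = map$n_undefined,
                 histogram = list(breaks = breaks, counts = counts)),
            class = "index_summary")
}

#' @export
print.index_summary <- function(x, ...) {
  cat(sprintf("<index_summary> %s: %.3f +/- %.3f (cv %s), range %.3f..%.3f, n = %d (%d undefined)\n",
              x$name, x$mean, x$sd,
              if (is.na(x$cv)) "NA" else sprintf("%.3f", x$cv),
              x$min, x$max, x$n_valid, x$n_undefined))
  invisible(x)
}

#' Fit an index-versus-concentration calibration model
#'
#' Ordinary least squares of index (response) on anthocyanin concentration
#' (predictor, ug per g fresh weight), either linear or quadratic.
#'
#' @param conc Numeric vector of measured concentrations (ug/g FW).
#' @param idx Numeric vector of per-sample index means, same length.
#' @param model `"linear"` or `"quadratic"`.
#' @return An object of class `antho_fit` with `coefficients`, `r_squared`,
#'   `rmse`, `aic`, `p_value`, `n`, the underlying `stats::lm` fit and the
#'   calibration ranges; supports `print`, `summary`, `coef`, `predict`,
#'   `fitted` and `residuals`.
#' @export
fit_index_model <- function(conc, idx, model = c("linear", "quadratic")) {
  model <- match.arg(model)
  conc <- as.numeric(conc); idx <- as.numeric(idx)
  if (length(conc) != length(idx)) stopf("conc and idx lengths differ")
  ok <- is.finite(conc) & is.finite(idx)
  if (!all(ok)) stopf("conc/idx contain non-finite values")
  n <- length(conc)
  p <- if (model == "linear") 2L else 3L
  if (n < p + 1L)
    stopf("need at least %d samples for a %s fit, got %d", p + 1L, model, n)
  if (stats::var(conc) == 0) stopf("degenerate design: constant predictor")
  if (stats::var(idx) == 0) stopf("zero-variance response")
  dat <- data.frame(conc = conc, idx = idx)
  fit <- if (model == "linear") stats::lm(idx ~ conc, data = dat)
         else stats::lm(idx ~ conc + I(conc^2), data = dat)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((idx - mean(idx))^2)
  k <- p + 1L  # coefficients + error variance
  fstat <- suppressWarnings(summary(fit)$fstatistic)
  p_value <- if (is.null(fstat) || anyNA(fstat)) NA_real_
             else unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                   lower.tail = FALSE))
  structure(list(model = model,
                 coefficients = stats::coef(fit),
                 r_squared = max(0, min(1, 1 - rss / tss)),
                 rmse = sqrt(rss / n),
                 aic = n * log(rss / n) + 2 * k,
                 p_value = p_value,
                 n = n, rss = rss, k = k,
                 lm = fit,
                 conc_range = range(conc),
                 idx_range = range(stats::fitted(fit)),
                 quadratic_infeasible = FALSE),
            class = "antho_fit")
}

#' @export
print.antho_fit <- function(x, digits = 4, ...) {
  eq <- if (x$model == "linear")
    sprintf("index = %.4g + %.4g * conc", x$coefficients[1L], x$coefficients[2L])
  else
    sprintf("index = %.4g + %.4g * conc + %.4g * conc^2",
            x$coefficients[1L], x$coefficients[2L], x$coefficients[3L])
  cat(sprintf("<antho_fit> %s (n = %d)\n  %s\n", x$model, x$n, eq))
  cat(sprintf("  R2 = %.*f, RMSE = %.4g, AIC = %.*f, p = %.3g\n",
              digits, x$r_squared, x$rmse, 1, x$aic, x$p_value))
  if (isTRUE(x$quadratic_infeasible))
    cat("  (quadratic fit infeasible at this sample size; linear returned)\n")
  invisible(x)
}

#' @export
summary.antho_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying least-squares fit:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.antho_fit <- function(object, ...) object$coefficients

#' @export
fitted.antho_fit <- function(object, ...) stats::fitted(object$lm)

#' @export
residuals.antho_fit <- function(object, ...) stats::residuals(object$lm)

#' Predict index values from concentrations
#'
#' @param object An [fit_index_model()] result.
#' @param conc Concentrations (ug/g FW) to evaluate the fitted curve at.
#' @param ... Unused.
#' @return Numeric vector of predicted index values.
#' @export
predict.antho_fit <- function(object, conc, ...) {
  unname(stats::predict(object$lm, newdata = data.frame(conc = as.numeric(conc))))
}

#' @export
plot.antho_fit <- function(x, ...) {
  dat <- x$lm$model
  graphics::plot(dat$conc, dat$idx,
                 xlab = "anthocyanin concentration (ug/g FW)",
                 ylab = "index", ...)
  cs <- seq(x$conc_range[1L], x$conc_range[2L], length.out = 200)
  graphics::lines(cs, predict(x, cs), col = "blue")
  invisible(x)
}

#' Select between linear and quadratic calibration by AIC
#'
#' Both models are fitted and the lower-AIC one returned; AIC ties (within
#' 1e-9) favor the linear model. When the quadratic fit is infeasible
#' (fewer than 4 samples) the linear fit is returned with its
#' `quadratic_infeasible` flag set.
#'
#' @inheritParams fit_index_model
#' @return An `antho_fit`.
#' @export
select_model <- function(conc, idx) {
  lin <- fit_index_model(conc, idx, "linear")
  if (length(conc) < 4L) {
    lin$quadratic_infeasible <- TRUE
    warning("too few samples for a quadratic fit; returning linear",
            call. = FALSE)
    return(lin)
  }
  # an (essentially) exact linear fit cannot be improved on; comparing AIC
  # of two machine-precision residual sums would be numerical noise
  if (lin$rmse <= 1e-12) return(lin)
  quad <- fit_index_model(conc, idx, "quadratic")
  if (quad$aic < lin$aic - 1e-9) quad else lin
}

#' Evaluate several indices against measured concentrations
#'
#' For every index column the linear/quadratic model is selected by AIC and
#' its statistics collected into one table sorted by ascending AIC (best
#' model first).
#'
#' @param table Data frame with a concentration column (named
#'   `concentration_ug_g` or `concentration`), optionally a `sample_id`
#'   column, and one numeric column per index.
#' @return A data frame with columns `Index`, `Model`, `R2`, `RMSE`, `AIC`,
#'   `p`, sorted by `AIC`; the selected fits are attached as attribute
#'   `fits`.
#' @export
compare_indices <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stopf("table must be a non-empty data frame")
  conc_col <- intersect(c("concentration_ug_g", "concentration"), names(table))
  if (length(conc_col) == 0L)
    stopf("table needs a 'concentration_ug_g' (or 'concentration') column")
  conc_col <- conc_col[1L]
  if (anyNA(table[[conc_col]])) stopf("missing concentrations in table")
  idx_cols <- setdiff(names(table), c(conc_col, "sample_id"))
  idx_cols <- idx_cols[vapply(table[idx_cols], is.numeric, TRUE)]
  if (length(idx_cols) == 0L) stopf("table has no numeric index columns")
  fits <- lapply(idx_cols, function(nm)
    select_model(table[[conc_col]], table[[nm]]))
  names(fits) <- idx_cols
  out <- data.frame(
    Index = idx_cols,
    Model = vapply(fits, `[[`, "", "model"),
    R2 = vapply(fits, `[[`, 0, "r_squared"),
    RMSE = vapply(fits, `[[`, 0, "rmse"),
    AIC = vapply(fits, `[[`, 0, "aic"),
    p = vapply(fits, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE)
  out <- out[order(out$AIC), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Invert a calibration fit: concentration from an index value
#'
#' Numerically inverts the fitted index-versus-concentration curve,
#' restricted to the calibration concentration range. The fit must be
#' strictly monotone over that range (a quadratic that turns around inside
#' the range is rejected) and the index value must lie within the fitted
#' index range.
#'
#' @param fit An `antho_fit`.
#' @param idx_value Index value(s) to invert.
#' @return Estimated concentration(s), ug/g FW.
#' @export
predict_concentration <- function(fit, idx_value) {
  if (!inherits(fit, "antho_fit")) stopf("fit must be an antho_fit")
  lo <- fit$conc_range[1L]; hi <- fit$conc_range[2L]
  if (fit$model == "quadratic") {
    b <- fit$coefficients[2L]; c2 <- fit$coefficients[3L]
    if (c2 != 0) {
      turn <- -b / (2 * c2)
      if (turn > lo && turn < hi)
        stopf("fit is non-monotone over the calibration range (turning point at %.4g)",
              turn)
    }
  }
  f_lo <- predict(fit, lo); f_hi <- predict(fit, hi)
  rng <- sort(c(f_lo, f_hi))
  vapply(as.numeric(idx_value), function(y) {
    if (y < rng[1L] - 1e-12 || y > rng[2L] + 1e-12)
      stopf("index value %.6g outside the fitted range [%.6g, %.6g]; refusing to extrapolate",
            y, rng[1L], rng[2L])
    y <- min(max(y, rng[1L]), rng[2L])
    if (abs(f_hi - f_lo) < 1e-300) return(lo)
    stats::uniroot(function(cc) predict(fit, cc) - y, lower = lo, upper = hi,
                   tol = 1e-10, extendInt = "no")$root
  }, 0)
}
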