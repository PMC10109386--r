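# Independent oracles used to cross-check the vectorized implementations.

# Scalar per-pixel index evaluation with plain arithmetic; returns a value
# matrix (NA where undefined or unmasked) computed one pixel at a time.
oracle_index <- function(name, g = NULL, r = NULL, n = NULL, mask = NULL) {
  ref <- g %||% r %||% n
  h <- nrow(ref); w <- ncol(ref)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j]) next
    gv <- if (!is.null(g)) g[i, j] else NA
    rv <- if (!is.null(r)) r[i, j] else NA
    nv <- if (!is.null(n)) n[i, j] else NA
    out[i, j] <- switch(name,
      NDAI = if (rv + gv == 0) NA else (rv - gv) / (rv + gv),
      NARI = if (gv == 0 || rv == 0) NA else
        (1 / gv - 1 / rv) / (1 / gv + 1 / rv),
      ARI = if (gv == 0 || rv == 0) NA else 1 / gv - 1 / rv,
      mACI = if (gv == 0) NA else nv / gv,
      mARI = if (gv == 0 || rv == 0) NA else (1 / gv - 1 / rv) * nv,
      RGI = if (gv == 0) NA else rv / gv)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Breadth-first 8-connected component labeling, one queue at a time.
oracle_label <- function(flags) {
  h <- nrow(flags); w <- ncol(flags)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (!flags[i0, j0] || lab[i0, j0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1L] + di; j <- p[2L] + dj
        if (i < 1 || i > h || j < 1 || j > w) next
        if (flags[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- nxt
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# Set-algebra binary erosion/dilation with a k x k box kernel.
oracle_erode <- function(flags, k) {
  h <- nrow(flags); w <- ncol(flags); half <- (k - 1L) / 2L
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rs <- (i - half):(i + half); cs <- (j - half):(j + half)
    rs <- rs[rs >= 1 & rs <= h]; cs <- cs[cs >= 1 & cs <= w]
    out[i, j] <- all(flags[rs, cs])
  }
  out
}

oracle_dilate <- function(flags, k) {
  h <- nrow(flags); w <- ncol(flags); half <- (k - 1L) / 2L
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rs <- (i - half):(i + half); cs <- (j - half):(j + half)
    rs <- rs[rs >= 1 & rs <= h]; cs <- cs[cs >= 1 & cs <= w]
    out[i, j] <- any(flags[rs, cs])
  }
  out
}

# Exhaustive Otsu threshold search: maximize between-class variance over all
# 8-bit candidate thresholds (mask = intensity > t).
oracle_otsu <- function(ints) {
  v <- as.vector(ints)
  best_t <- NA_real_; best_var <- -Inf
  for (t in 0:254) {
    hi <- v > t
    n1 <- sum(hi); n0 <- length(v) - n1
    if (n0 == 0L || n1 == 0L) next
    bc <- (n0 / length(v)) * (n1 / length(v)) * (mean(v[hi]) - mean(v[!hi]))^2
    if (bc > best_var) { best_var <- bc; best_t <- t }
  }
  best_t
}

# Polynomial least squares by the closed-form normal equations.
oracle_polyfit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Small reflectance-map constructors for index tests.
rmap <- function(values, h = 1, w = length(values)) {
  reflectance_map(matrix(values, h, w))
}
bimg <- function(values, h = 1, w = length(values), peak = 516, fwhm = 40) {
  band_image(matrix(as.integer(values), h, w), peak, fwhm)
}
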