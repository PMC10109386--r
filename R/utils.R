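# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-away-from-zero rounding (base round() is round-half-even, which would
# bias 8-bit quantization at the .5 boundaries).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stopf("%s have mismatched dimensions: %s vs %s", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
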