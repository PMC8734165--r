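# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# row-wise softmax with the usual max-shift for stability
softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# backward through a row-wise softmax: given p and dL/dp, return dL/dlogits
softmax_rows_backward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}
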