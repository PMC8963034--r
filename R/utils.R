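# internal helpers

# Derive a child RNG seed (< 2^31) from a root seed and integer stream tags.
# All randomness in the package flows from one root seed through this
# function, so cohorts are byte-identical across runs and platforms.
derive_seed <- function(root, ...) {
  parts <- c(root, ...)
  s <- 0
  for (x in parts) {
    s <- (s * 69069 + (x + 1) * 40503) %% 2147483647
    s <- (s * 69069 + 12345) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
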