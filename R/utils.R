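# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  }
  force(code)
}

# n child seeds derived deterministically from one master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n, replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
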