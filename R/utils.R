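# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. seed = NULL uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw n child seeds from the current stream; keeps every derived seed
# within the 32-bit integer range.
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# STD values live on a fixed millisecond grid.
on_grid <- function(x, step) {
  is.numeric(x) & is.finite(x) & x > 0 & (x %% step == 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
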