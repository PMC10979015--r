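# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds from one user seed, kept below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Maximum-intensity projection of a (z, y, x) stack along z.
max_project <- function(stack) {
  stopifnot(length(dim(stack)) == 3L)
  apply(stack, c(2L, 3L), max)
}

geomean_impl <- function(x) exp(mean(log(x)))
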