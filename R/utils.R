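# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points funnel
# through this so that identical (inputs, seed) give identical results
# without clobbering the user's RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Root-mean-square of a residual vector.
rms <- function(x) sqrt(mean(x^2))
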