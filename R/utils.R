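# Internal helpers shared across the pipeline.

# Seed the RNG locally: restores the caller's .Random.seed on exit so that
# seeded package functions compose without clobbering user state.
local_rng <- function(seed, kind = "Mersenne-Twister") {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed, kind = kind)
  parent <- parent.frame()
  defer <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  do.call(on.exit, list(substitute(defer()), add = TRUE), envir = parent)
  invisible(seed)
}

# Derive a stream-specific 31-bit sub-seed from a master seed (double
# arithmetic to avoid integer overflow; result always a valid seed).
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %%
               2147483629)
}

# Stationary AR(1) series with unit marginal variance; innovations N(0,1-rho^2).
# x may be a matrix (t x n): each column an independent series.
ar1_noise <- function(nt, n, rho) {
  z <- matrix(stats::rnorm(nt * n), nt, n)
  if (rho == 0) return(z)
  z <- z * sqrt(1 - rho^2)
  z[1, ] <- stats::rnorm(n)  # stationary start
  out <- stats::filter(z, rho, method = "recursive")  # column-wise recursion
  matrix(as.numeric(out), nt, n)
}

# Clip correlations away from +/-1 before the Fisher transform.
fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

`%||%` <- function(a, b) if (is.null(a)) b else a
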