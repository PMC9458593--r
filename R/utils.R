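#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb
# user-level reproducibility.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}
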