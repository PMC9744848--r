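# Seed plumbing.  A single experiment seed fans out into named per-component
# streams so that toggling one component (e.g. place input) never shifts the
# random draws of another.

STREAM_OFFSETS <- c(trajectory = 101L, landmarks = 211L, place_init = 307L,
                    grid_init = 401L, noise = 503L, fixed_fields = 601L,
                    calibration = 701L)

derive_seed <- function(seed, stream) {
  off <- STREAM_OFFSETS[[stream]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
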