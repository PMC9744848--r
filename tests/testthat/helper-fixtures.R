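# Shared fixtures, built in code.  Heavy shared objects are memoised so the
# acceptance tests that share a simulation do not recompute it.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# a settled small-gain module reused across grid tests
settled_module <- function(gain = 0.05, seed = 3) {
  memo(sprintf("mod_%g_%d", gain, seed),
       init_activity(grid_module(gain = gain), seed = seed, burn_in = 500))
}

# synthetic rate map: Gaussian firing fields on a hexagonal or square lattice
lattice_rate_map <- function(type = c("hex", "square"), spacing = 20,
                             L = 100, bin = 2.5, angle = 0, sd_field = 4) {
  type <- match.arg(type)
  basis <- if (type == "hex")
    rbind(c(1, 0), c(0.5, sqrt(3) / 2)) * spacing
  else rbind(c(1, 0), c(0, 1)) * spacing
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  basis <- basis %*% t(rot)
  ctr <- expand.grid(a = -8:8, b = -8:8)
  pts <- as.matrix(ctr) %*% basis
  pts <- sweep(pts, 2, c(L / 2, L / 2), "+")
  nb <- round(L / bin)
  g <- expand.grid(x = (seq_len(nb) - 0.5) * bin, y = (seq_len(nb) - 0.5) * bin)
  val <- rep(0, nrow(g))
  for (k in seq_len(nrow(pts))) {
    d2 <- (g$x - pts[k, 1])^2 + (g$y - pts[k, 2])^2
    val <- val + exp(-d2 / (2 * sd_field^2))
  }
  matrix(val, nb, nb)
}

# circularly symmetric map (value a function of radius only)
radial_map <- function(nb = 40, bin = 2.5) {
  g <- expand.grid(x = seq_len(nb) - 0.5, y = seq_len(nb) - 0.5)
  r <- sqrt((g$x - nb / 2)^2 + (g$y - nb / 2)^2) * bin
  matrix(cos(r / 4) * exp(-r / 60), nb, nb)
}

default_arena <- function() memo("arena_default", arena())

# the standard full-length coupled exploration, shared across test files
full_run <- function() {
  memo("full_run_seed1",
       run_simulation(experiment_config(n_steps = 10000, seed = 1)))
}
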