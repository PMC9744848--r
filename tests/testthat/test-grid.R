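test_that("torus displacement equals exhaustive lattice search", {
  Py <- sqrt(3) / 2
  # worked wrap example
  expect_equal(torus_displacement(c(0.95, 0.3), c(0.05, 0.3)), c(-0.10, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(torus_displacement(c(0.2, 0.5), c(0.2, 0.5)), c(0, 0),
               ignore_attr = TRUE)
  # exhaustive oracle over a 9x9 block of lattice shifts
  set.seed(4)
  n <- 2000
  ci <- cbind(runif(n), runif(n, 0, Py))
  cj <- cbind(runif(n), runif(n, 0, Py))
  d <- torus_displacement(ci, cj)
  sh <- expand.grid(m = -4:4, n = -4:4)
  brute <- sapply(seq_len(n), function(k) {
    dx <- ci[k, 1] - cj[k, 1] + sh$m + 0.5 * sh$n
    dy <- ci[k, 2] - cj[k, 2] + sh$n * Py
    min(dx^2 + dy^2)
  })
  expect_equal(rowSums(d^2), brute, tolerance = 1e-12)
})

test_that("recurrent weights have the stated structure", {
  mod <- grid_module(gain = 0.05)
  W <- build_weights(mod, c(0, 0))
  expect_equal(unname(diag(W)), rep(mod$I_a - mod$T_shift, 400))
  expect_equal(W, t(W), tolerance = 1e-12)      # symmetric at v = 0
  expect_true(all(W >= -mod$T_shift - 1e-12 &
                    W <= mod$I_a - mod$T_shift + 1e-12))
  # far-separated neurons sit at the inhibition floor
  co <- mod$coords
  far <- which.max(rowSums(torus_displacement(
    cbind(co$cx, co$cy), matrix(rep(c(co$cx[1], co$cy[1]), 400), ncol = 2,
                                byrow = TRUE))^2))
  expect_lt(abs(W[1, far] - (-mod$T_shift)), 2e-3)
})

test_that("a CAN step matches a literal transcription of the update", {
  # 2x2 toy network, hand-checkable
  toy <- grid_module(gain = 0.1, Nx = 2, Ny = 2)
  toy$A <- c(0.1, 0.3, 0.2, 0.4)
  v <- c(0.3, -0.2)
  W <- build_weights(toy, toy$gain * v)
  B <- as.numeric(toy$A %*% W)
  ref <- pmax(0, B + toy$tau * (B / mean(B) - B))
  out <- can_run(toy, v[1], v[2])
  expect_equal(out$A, ref, tolerance = 1e-12)
  # and on the full-size module with a random state
  mod <- settled_module()
  v2 <- c(0.9, -0.55)
  W2 <- build_weights(mod, mod$gain * v2)
  B2 <- as.numeric(mod$A %*% W2)
  ref2 <- pmax(0, B2 + mod$tau * (B2 / mean(B2) - B2))
  expect_equal(can_run(mod, v2[1], v2[2])$A, ref2, tolerance = 1e-10)
})

test_that("initial activity is uniform below 1/sqrt(N) and settles to one bump", {
  mod <- grid_module(gain = 0.05)
  raw <- init_activity(mod, seed = 21, burn_in = 0)
  expect_true(all(raw$A >= 0 & raw$A <= 0.05))
  expect_identical(init_activity(mod, seed = 21, burn_in = 0)$A, raw$A)
  set <- settled_module(seed = 3)
  A <- matrix(set$A, 20, 20)
  # count wrapped local maxima above half the global max
  nmax <- 0
  for (i in 1:20) for (j in 1:20) {
    nb <- A[(i + -1:1 - 1) %% 20 + 1, (j + -1:1 - 1) %% 20 + 1]
    if (A[i, j] >= max(nb) && A[i, j] > 0.5 * max(A)) nmax <- nmax + 1
  }
  expect_equal(nmax, 1)
})

test_that("the bump is stationary without velocity input", {
  mod <- settled_module()
  r <- can_run(mod, rep(0, 200), rep(0, 200))
  drift <- sqrt(sum(torus_displacement(r$centers[200, ], r$centers[1, ])^2))
  expect_lt(drift, 0.01)
  # total activity varies by < 1% over a long zero-velocity run
  r2 <- can_run(mod, rep(0, 1000), rep(0, 1000), record_activity = TRUE)
  tot <- rowSums(r2$activity)
  expect_lt((max(tot) - min(tot)) / mean(tot), 0.01)
})

test_that("bump center follows the circular-mean contract", {
  mod <- grid_module(gain = 0.05)
  co <- mod$coords
  # single active neuron -> its coordinates
  mod$A <- rep(0, 400); mod$A[137] <- 1
  expect_equal(bump_center(mod), c(co$cx[137], co$cy[137]), tolerance = 1e-12)
  # two equal masses near the x-wrap average to 0, not 0.5
  mod$A <- rep(0, 400)
  i1 <- which(abs(co$cx - 0.125) < 1e-9 & abs(co$cy - co$cy[1]) < 1e-9)[1]
  i2 <- which(abs(co$cx - 0.875) < 1e-9 & abs(co$cy - co$cy[1]) < 1e-9)[1]
  mod$A[c(i1, i2)] <- 1
  ctr <- bump_center(mod)
  expect_true(min(ctr[1], 1 - ctr[1]) < 1e-9)
  # settled bump center lies within half a neuron pitch of the argmax
  set <- settled_module()
  ctr2 <- bump_center(set)
  k <- which.max(set$A)
  d <- torus_displacement(ctr2, c(co$cx[k], co$cy[k]))
  expect_lt(sqrt(sum(d^2)), 0.5 / 20 * sqrt(2))
  mod$A <- rep(0, 400)
  expect_error(bump_center(mod), "zero activity")
})

test_that("position integration and gamma calibration are consistent", {
  expect_equal(integrate_position(c(1, 2), c(0, 0), 5), c(1, 2))
  expect_equal(integrate_position(c(1, 2), c(0.5, -0.25), 2), c(2, 1.5))
  mod <- settled_module()
  g1 <- calibrate_gamma(mod)
  g2 <- calibrate_gamma(mod)
  expect_identical(g1, g2)
  # the bump moves ~ gain * v per step, so gamma ~ 1/gain
  expect_equal(g1, 1 / mod$gain, tolerance = 0.05)
  # self-consistency: 100-step straight run lands within 10% of the distance
  n <- 100; sp <- 0.8
  r <- can_run(mod, rep(sp, n), rep(0, n))
  d <- torus_displacement(r$centers[-1, ], r$centers[-n, ], mod$coords$Py)
  endpoint <- g1 * colSums(d)
  expect_lt(sqrt(sum((endpoint - c(sp * (n - 1), 0))^2)), 0.1 * sp * n)
})

test_that("closed-loop integration returns near the start", {
  mod <- settled_module()
  g <- calibrate_gamma(mod)
  n <- 150; sp <- 0.5
  vx <- rep(c(sp, 0, -sp, 0), each = n)
  vy <- rep(c(0, sp, 0, -sp), each = n)
  r <- can_run(mod, vx, vy)
  d <- torus_displacement(r$centers[-1, ], r$centers[-(4 * n), ],
                          mod$coords$Py)
  ret <- g * colSums(d)
  # return error below 5% of path length
  expect_lt(sqrt(sum(ret^2)), 0.05 * 4 * n * sp)
})

test_that("velocity rotation equivariance holds at zero bias", {
  mod <- settled_module()
  g <- calibrate_gamma(mod)
  th <- pi / 3
  n <- 120; sp <- 0.6
  r1 <- can_run(mod, rep(sp, n), rep(0, n))
  r2 <- can_run(mod, rep(sp * cos(th), n), rep(sp * sin(th), n))
  path <- function(r) {
    d <- torus_displacement(r$centers[-1, ], r$centers[-n, ], mod$coords$Py)
    g * colSums(d)
  }
  p1 <- path(r1); p2 <- path(r2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(p2, as.numeric(R %*% p1), tolerance = 0.08 * sp * n)
})

test_that("higher gain gives denser grids (smaller field spacing)", {
  ar <- default_arena()
  tr <- memo("traj_spacing",
             generate_trajectory("center_biased", 6000, ar, seed = 6))
  v <- trajectory_velocities(tr)
  spacing <- sapply(c(0.04, 0.05, 0.06, 0.07, 0.08), function(gain) {
    mod <- init_activity(grid_module(gain = gain), seed = 8, burn_in = 400)
    r <- can_run(mod, v[, 1], v[, 2], record_activity = TRUE)
    rm <- rate_map(tr$x, tr$y, r$activity[, 200], 100)
    ac <- autocorrelogram(rm)
    pk <- placegrid:::autocorr_peaks(ac)
    pk <- pk[order(pk[, "dist"]), , drop = FALSE]
    median(pk[seq_len(min(6, nrow(pk))), "dist"]) * rm$bin_size
  })
  expect_true(all(diff(spacing) < 0))
})

test_that("module stack is ordered dorsal to ventral with scaled gammas", {
  stack <- memo("stack_seed1", module_stack(seed = 1))
  gam <- vapply(stack$modules, function(m) m$gamma, 0)
  expect_equal(length(stack$modules), 5)
  # gamma ~ 0.95^m / gain
  expect_equal(gam, 0.95^(1:5) / c(0.04, 0.05, 0.06, 0.07, 0.08),
               tolerance = 0.05)
  # uncorrected error grows with path length (late mean exceeds early mean)
  ar <- default_arena()
  tr <- generate_trajectory("center_biased", 1000, ar, seed = 2)
  gr <- stack_run(stack, tr)
  truth <- cbind(tr$x, tr$y)
  for (m in 1:5) {
    err <- sqrt(rowSums((gr$positions[[m]] - truth)^2))
    expect_gt(mean(err[501:1000]), mean(err[1:500]))
  }
})
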