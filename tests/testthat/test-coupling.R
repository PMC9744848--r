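test_that("grid drive equals the literal max-multiply-mean transcription", {
  set.seed(12)
  nc <- 40
  W <- gp_weight_matrix(nc, 5)
  expect_true(all(W >= 0 & W <= 1))
  maxA <- runif(5, 0, 20)
  drive <- grid_drive(maxA, W)
  naive <- sapply(seq_len(nc), function(j)
    mean(sapply(1:5, function(m) maxA[m] * W[j, m])))
  expect_equal(drive, naive, tolerance = 1e-12)
  # all-zero activity -> zero drive, condition (ii) fails everywhere
  expect_equal(grid_drive(rep(0, 5), W), rep(0, nc))
  # uniform weights of 1 and unit maxima -> drive exactly 1
  expect_equal(grid_drive(rep(1, 5), matrix(1, 3, 5)), rep(1, 3))
})

test_that("emergence gate is the three-way conjunction", {
  expect_true(emergence_gate(TRUE, 1.2, 0.9, A_thr = 0.5))
  expect_false(emergence_gate(TRUE, 1.0, 0.9, A_thr = 0.5))  # drive at 1.0
  expect_false(emergence_gate(FALSE, 2.0, 0.9, A_thr = 0.5)) # no spike
  expect_false(emergence_gate(TRUE, 2.0, 0.4, A_thr = 0.5))  # features fail
  # vectorised over cells
  g <- emergence_gate(c(TRUE, TRUE, FALSE), c(1.2, 1.05, 3), c(1, 1, 1), 0.5)
  expect_equal(g, c(TRUE, FALSE, FALSE))
})

test_that("cross-module uncertainty uses the sample-sd composition", {
  same <- matrix(rep(c(3, 4), each = 5), 5, 2)
  expect_equal(estimate_error(same), 0)
  two <- rbind(c(0, 7), c(2, 7))
  expect_equal(estimate_error(two), sqrt(2), tolerance = 1e-12)
  expect_error(estimate_error(rbind(c(1, 2))), ">= 2")
  set.seed(3)
  pm <- matrix(rnorm(10), 5, 2)
  expect_equal(estimate_error(pm), sqrt(sd(pm[, 1])^2 + sd(pm[, 2])^2))
})

test_that("position corrections snap all modules within the radius only", {
  pos_m <- rbind(c(10, 10), c(12, 9), c(8, 11))
  centers <- rbind(c(50, 50), c(11, 10.5))
  # nearest center 3.0 away -> unchanged
  r1 <- correct_position(pos_m, centers, pos_true = c(11, 13.5),
                         snap_radius = 2.5)
  expect_equal(r1$pos_m, pos_m)
  expect_null(r1$event)
  # nearest center 1.0 away -> all modules reset to it
  r2 <- correct_position(pos_m, centers, pos_true = c(11, 11.5),
                         snap_radius = 2.5)
  expect_equal(r2$pos_m, matrix(rep(c(11, 10.5), each = 3), 3, 2))
  expect_equal(r2$event$distance, 1)
  expect_equal(r2$event$index, 2)
  # no fields -> identity
  r3 <- correct_position(pos_m, NULL, c(0, 0))
  expect_equal(r3$pos_m, pos_m)
  # equidistant centers break ties to the lowest index
  eq <- rbind(c(0, 1), c(0, -1))
  r4 <- correct_position(pos_m, eq, c(0, 0), snap_radius = 2.5)
  expect_equal(r4$event$index, 1)
})

test_that("grid-to-place plasticity contracts active rows to the signal", {
  W <- matrix(0, 4, 5)
  X <- c(50, 50, 50)
  W1 <- update_gp_weights(W, X, active = 2, mu = 0.001)
  expect_equal(W1[2, ], rep(0.05, 5))   # mu * mean(X')
  expect_equal(W1[1, ], rep(0, 5))
  # fixed point
  Wf <- matrix(50, 4, 5)
  expect_equal(update_gp_weights(Wf, X, 1:4), Wf)
  # geometric convergence
  W2 <- matrix(0, 1, 5)
  for (k in 1:100) W2 <- update_gp_weights(W2, X, 1, mu = 0.01)
  expect_equal(W2[1, 1], 50 * (1 - (1 - 0.01)^100), tolerance = 1e-10)
})

test_that("identical config and seed reproduce the run exactly", {
  cf <- experiment_config(n_steps = 120, n_cells = 120, seed = 7)
  r1 <- run_simulation(cf)
  r2 <- run_simulation(cf)
  expect_identical(r1$module_error, r2$module_error)
  expect_identical(r1$corrections, r2$corrections)
  expect_identical(r1$n_fields, r2$n_fields)
  expect_identical(r1$decoded, r2$decoded)
})

test_that("without place input the estimates are pure path integration", {
  cf_on <- experiment_config(n_steps = 150, n_cells = 100, seed = 3)
  on <- run_simulation(cf_on)
  off <- run_simulation(experiment_config(n_steps = 150, n_cells = 100,
                                          seed = 3, place_input = FALSE),
                        stack = on$stack, traj = on$trajectory)
  for (m in 1:5)
    expect_equal(off$estimates[[m]], unname(on$pure_estimates[[m]]),
                 ignore_attr = TRUE)
  expect_equal(nrow(off$corrections), 0)
})

test_that("fixed-field mode draws the requested centers inside the arena", {
  cf <- experiment_config(n_steps = 100, seed = 11, field_mode = "fixed",
                          n_fixed_fields = 200)
  r <- run_simulation(cf)
  expect_equal(nrow(r$field_centers), 200)
  expect_true(all(r$field_centers >= 0 & r$field_centers <= 100))
  expect_equal(unique(r$n_fields), 200L)
  # same seed -> identical centers
  r2 <- run_simulation(cf)
  expect_identical(r$field_centers, r2$field_centers)
})

test_that("corrections never leave the estimate further than the snap radius", {
  cf <- experiment_config(n_steps = 400, seed = 5, field_mode = "fixed",
                          n_fixed_fields = 150)
  r <- run_simulation(cf)
  expect_gt(nrow(r$corrections), 0)
  # at a correction step the post-correction error equals the snap distance
  for (k in seq_len(min(10, nrow(r$corrections)))) {
    t <- r$corrections$t[k]
    err_t <- r$module_error[t, ]
    expect_true(all(err_t <= cf$snap_radius + 1e-9))
    expect_equal(unname(err_t[1]), r$corrections$distance[k],
                 tolerance = 1e-9)
  }
})

test_that("emergent fields appear preferentially at uncertain positions", {
  r <- run_simulation(experiment_config(n_steps = 600, n_cells = 400,
                                        seed = 2))
  expect_gt(max(r$n_fields), 0)
  emerged <- which(diff(c(0, r$n_fields)) > 0)
  frac_unc_emerge <- mean(r$uncertain[emerged])
  expect_gte(frac_unc_emerge, mean(r$uncertain))
})

test_that("place decoding error trends downward as fields develop", {
  r <- run_simulation(experiment_config(n_steps = 800, n_cells = 500,
                                        seed = 6))
  err <- r$decoded[, "err_norm"]
  early <- mean(err[1:160], na.rm = TRUE)
  late <- mean(err[641:800], na.rm = TRUE)
  expect_lt(late, early)
})

test_that("place-field peaks move more before the plateau than after", {
  r <- full_run()
  nf <- r$n_fields
  plateau <- which(nf >= 0.95 * nf[length(nf)])[1]
  shifts <- r$peak_shift
  shifts[is.na(shifts)] <- 0            # steps with no peak movement
  before <- mean(shifts[seq_len(plateau)])
  after <- mean(shifts[(plateau + 1):length(shifts)])
  expect_gt(before, after)
})
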