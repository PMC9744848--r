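#' Twisted-torus neuron coordinates
#'
#' Neurons sit on an `Nx x Ny` sheet with positions
#' `c_x = (l_x - 0.5)/Nx`, `c_y = (sqrt(3)/2)(l_y - 0.5)/Nx`, so the
#' fundamental domain is `[0, 1) x [0, Py)` with `Py = (sqrt(3)/2) Ny/Nx`.
#' The sheet wraps as a twisted torus: the tiling lattice is generated by
#' `e1 = (1, 0)` and `e2 = (0.5, Py)`.
#'
#' @param Nx,Ny Sheet dimensions (Nx must be even; default 20 x 20).
#' @return List `cx, cy, lx, ly, Nx, Ny, Py`.
#' @export
torus_coords <- function(Nx = 20, Ny = 20) {
  stopifnot(Nx >= 2, Ny >= 1, Nx %% 2 == 0)
  l <- seq_len(Nx * Ny)
  lx <- ((l - 1) %% Nx) + 1
  ly <- ((l - 1) %/% Nx) + 1
  list(cx = (lx - 0.5) / Nx, cy = (sqrt(3) / 2) * (ly - 0.5) / Nx,
       lx = lx, ly = ly, Nx = Nx, Ny = Ny,
       Py = (sqrt(3) / 2) * Ny / Nx)
}

torus_shifts <- function(Py = sqrt(3) / 2) {
  g <- expand.grid(m = -2:2, n = -2:2)
  cbind(sx = g$m + 0.5 * g$n, sy = g$n * Py)
}

#' Minimal displacement on the twisted torus
#'
#' Returns `c_i - c_j + s` for the tiling shift `s` (integer combination of
#' `e1 = (1,0)` and `e2 = (0.5, Py)`) that minimises the Euclidean norm.
#'
#' @param ci,cj Length-2 points, or n x 2 matrices, in the fundamental domain.
#' @param Py Domain height (default `sqrt(3)/2`).
#' @return Displacement(s), same shape as the input.
#' @export
torus_displacement <- function(ci, cj, Py = sqrt(3) / 2) {
  ci <- rbind(ci); cj <- rbind(cj)
  d <- ci - cj
  sh <- torus_shifts(Py)
  best <- matrix(Inf, nrow(d), 1)
  out <- d
  for (k in seq_len(nrow(sh))) {
    ax <- d[, 1] + sh[k, 1]; ay <- d[, 2] + sh[k, 2]
    n2 <- ax^2 + ay^2
    upd <- n2 < best[, 1]
    best[upd, 1] <- n2[upd]
    out[upd, 1] <- ax[upd]; out[upd, 2] <- ay[upd]
  }
  if (nrow(out) == 1) drop(out) else out
}

# Displacement classes: weights depend only on neuron index differences.
# Wrapping the row difference by Ny is equivalent (modulo the tiling lattice)
# to shifting the column difference by Nx/2 -- the "twist".
torus_class_table <- function(coords) {
  Nx <- coords$Nx; Ny <- coords$Ny
  dlx <- outer(coords$lx, coords$lx, "-")
  dly <- outer(coords$ly, coords$ly, "-")
  dy_m <- dly %% Ny
  k <- (dly - dy_m) / Ny
  dx_eff <- (dlx - k * (Nx / 2)) %% Nx
  cls <- dx_eff + Nx * dy_m
  a <- 0:(Nx - 1); b <- 0:(Ny - 1)
  g <- expand.grid(a = a, b = b)
  list(cls = matrix(as.integer(cls), Nx * Ny, Nx * Ny),
       repx = g$a / Nx, repy = (sqrt(3) / 2) * g$b / Nx)
}

#' A twisted-torus continuous-attractor grid module
#'
#' One grid module: `N = Nx x Ny` neurons, Gaussian center-surround weights
#' `w_ij = I_a exp(-||c_i - c_j + v^R||^2 / sigma_w^2) - T` (twisted-torus
#' norm), activity update `A <- f(B + tau (B/mean(B) - B))` with transfer
#' `B_j = sum_i A_i w_ij` and rectification `f`.  Velocity enters the weights
#' as `v^R = gain * R_beta * v`.
#'
#' @param gain Velocity gain (one of 0.04 ... 0.08 in the standard stack).
#' @param Nx,Ny Sheet size (default 20 x 20).
#' @param I_a Activation intensity (default 0.3).
#' @param sigma_w Weight Gaussian width (default 0.24).
#' @param T_shift Inhibition shift (default 0.05).
#' @param tau Stabilisation strength in `[0, 1)` (default 0.95).
#' @param beta Bias (grid-orientation) angle in radians (default 0).
#' @return An object of class `grid_module`.
#' @export
grid_module <- function(gain, Nx = 20, Ny = 20, I_a = 0.3, sigma_w = 0.24,
                        T_shift = 0.05, tau = 0.95, beta = 0) {
  stopifnot(gain > 0, tau >= 0, tau < 1, I_a > 0, sigma_w > 0)
  coords <- torus_coords(Nx, Ny)
  ct <- torus_class_table(coords)
  structure(list(coords = coords, cls = ct$cls, repx = ct$repx,
                 repy = ct$repy, gain = gain, I_a = I_a, sigma_w = sigma_w,
                 T_shift = T_shift, tau = tau, beta = beta,
                 A = NULL, gamma = NA_real_), class = "grid_module")
}

#' @export
print.grid_module <- function(x, ...) {
  cat(sprintf("<grid_module> %dx%d neurons, gain=%.3g, gamma=%s\n",
              x$coords$Nx, x$coords$Ny, x$gain,
              if (is.na(x$gamma)) "uncalibrated" else sprintf("%.3g", x$gamma)))
  invisible(x)
}

rotate_velocity <- function(v, gain, beta) {
  R <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2, 2)
  gain * as.numeric(R %*% v)
}

#' Recurrent weight matrix for a given modulated velocity
#'
#' Direct (per-pair) evaluation of
#' `w_ij = I_a exp(-||c_i - c_j + v_R||^2 / sigma_w^2) - T` with the
#' twisted-torus minimal norm.  Symmetric at `v_R = 0`.
#'
#' @param module A [grid_module()].
#' @param v_R Modulated velocity (already multiplied by gain/rotation).
#' @return N x N weight matrix.
#' @export
build_weights <- function(module, v_R = c(0, 0)) {
  co <- module$coords
  N <- co$Nx * co$Ny
  dx <- outer(co$cx, co$cx, "-") + v_R[1]
  dy <- outer(co$cy, co$cy, "-") + v_R[2]
  sh <- torus_shifts(co$Py)
  n2 <- matrix(Inf, N, N)
  for (k in seq_len(nrow(sh)))
    n2 <- pmin(n2, (dx + sh[k, 1])^2 + (dy + sh[k, 2])^2)
  module$I_a * exp(-n2 / module$sigma_w^2) - module$T_shift
}

#' Initialise module activity and settle the bump
#'
#' Activity is drawn i.i.d. from `U(0, 1/sqrt(N))`; `burn_in` zero-velocity
#' update steps then let a single stable activity bump form on the sheet.
#'
#' @param module A [grid_module()].
#' @param seed Integer seed.
#' @param burn_in Number of zero-velocity settling steps (default 500).
#' @return The module with its `A` slot set.
#' @export
init_activity <- function(module, seed = 1L, burn_in = 500) {
  N <- module$coords$Nx * module$coords$Ny
  A0 <- with_seed(seed, stats::runif(N, 0, 1 / sqrt(N)))
  module$A <- A0
  if (burn_in > 0) {
    r <- can_run(module, rep(0, burn_in), rep(0, burn_in))
    module$A <- r$A
  }
  module
}

#' Run the module over a velocity sequence
#'
#' @param module Initialised [grid_module()].
#' @param vx,vy Raw planar velocities (a.u./step); gain and bias rotation are
#'   applied internally.
#' @param record_activity Return the full activity trace (steps x N)?
#' @return List: `activity` (if recorded), `centers` (steps x 2 bump centers
#'   in torus coordinates), `max_activity`, and `A` (final activity).
#' @export
can_run <- function(module, vx, vy, record_activity = FALSE) {
  if (is.null(module$A)) stop("module not initialised; call init_activity()")
  R <- matrix(c(cos(module$beta), sin(module$beta),
                -sin(module$beta), cos(module$beta)), 2, 2)
  vr <- cbind(vx, vy) %*% t(R) * module$gain
  can_run_cpp(module$A, module$cls, module$repx, module$repy,
              vr[, 1], vr[, 2], module$I_a, module$sigma_w, module$T_shift,
              module$tau, module$coords$Py, module$coords$cx,
              module$coords$cy, record_activity)
}

#' Single CAN update step
#'
#' @param module Initialised module.
#' @param v Raw planar velocity for this step.
#' @return The module with updated activity.
#' @export
can_step <- function(module, v = c(0, 0)) {
  r <- can_run(module, v[1], v[2])
  module$A <- r$A
  module
}

#' Activity bump center
#'
#' Activity-weighted circular mean, computed independently per periodic
#' coordinate by the resultant-vector (angle) method and mapped back to the
#' fundamental domain.
#'
#' @param module An initialised module (or a list with `A` and `coords`).
#' @return Length-2 center in torus coordinates.
#' @export
bump_center <- function(module) {
  A <- module$A; co <- module$coords
  if (is.null(A) || sum(A) <= 0) stop("bump center undefined: zero activity")
  angx <- atan2(sum(A * sin(2 * pi * co$cx)), sum(A * cos(2 * pi * co$cx)))
  angy <- atan2(sum(A * sin(2 * pi * co$cy / co$Py)),
                sum(A * cos(2 * pi * co$cy / co$Py)))
  x <- angx / (2 * pi); if (x < 0) x <- x + 1
  y <- angy / (2 * pi); if (y < 0) y <- y + 1
  c(x, y * co$Py)
}

#' Path-integration update from a bump displacement
#'
#' `pos(t+1) = pos(t) + gamma * delta`, where `delta` is the bump-center
#' displacement on the torus between consecutive steps.
#'
#' @param pos_prev Previous position estimate (length 2).
#' @param delta_bump Bump displacement (torus units).
#' @param gamma Spacing/scale factor from [calibrate_gamma()].
#' @export
integrate_position <- function(pos_prev, delta_bump, gamma) {
  pos_prev + gamma * delta_bump
}

#' Calibrate the torus-to-arena scale factor gamma
#'
#' Drives the settled module along two straight constant-velocity legs (one
#' per axis) of known displacement and estimates, by least squares, the scalar
#' `gamma` mapping bump-center displacement to arena displacement.
#'
#' @param module Initialised module.
#' @param speed Calibration speed (a.u./step, default 0.5).
#' @param n_steps Steps per leg (default 200).
#' @return `gamma` (scalar).
#' @export
calibrate_gamma <- function(module, speed = 0.5, n_steps = 200) {
  if (is.null(module$A)) stop("module not initialised")
  num <- 0; den <- 0
  for (dir in list(c(1, 0), c(0, 1))) {
    r <- can_run(module, rep(speed * dir[1], n_steps),
                 rep(speed * dir[2], n_steps))
    cen <- r$centers
    d <- torus_displacement(cen[-1, , drop = FALSE],
                            cen[-n_steps, , drop = FALSE],
                            module$coords$Py)
    dt <- matrix(rep(speed * dir, each = n_steps - 1), ncol = 2)
    num <- num + sum(d * dt)
    den <- den + sum(d * d)
  }
  if (den <= 1e-12) stop("calibration failed: bump did not move")
  num / den
}

#' Build and calibrate the five-module dorsal-to-ventral grid stack
#'
#' Five modules share topology and orientation but use increasing velocity
#' gains (denser grids towards the ventral end).  Each module settles its
#' bump, is calibrated with [calibrate_gamma()], and the inter-module spacing
#' factor (default 0.95) is applied multiplicatively along the stack.
#'
#' @param gains Velocity gains, dorsal to ventral.
#' @param seed Integer seed (per-module init seeds are derived from it).
#' @param spacing_factor Consecutive-module spacing ratio applied to the
#'   calibrated gamma (`gamma_m = gamma * spacing_factor^m`; default 0.95).
#'   Every module carries a share of the mis-scale, so all modules accumulate
#'   position error without place-field correction, dorsal least and ventral
#'   most.
#' @param burn_in Settling steps per module.
#' @param ... Passed to [grid_module()].
#' @return An object of class `module_stack` (list of modules + gammas).
#' @export
module_stack <- function(gains = c(0.04, 0.05, 0.06, 0.07, 0.08), seed = 1L,
                         spacing_factor = 0.95, burn_in = 500, ...) {
  mods <- vector("list", length(gains))
  for (m in seq_along(gains)) {
    mod <- grid_module(gain = gains[m], ...)
    mod <- init_activity(mod, seed = derive_seed(seed, "grid_init") + m,
                         burn_in = burn_in)
    mod$gamma <- calibrate_gamma(mod) * spacing_factor^m
    mods[[m]] <- mod
  }
  structure(list(modules = mods, gains = gains,
                 spacing_factor = spacing_factor), class = "module_stack")
}

#' @export
print.module_stack <- function(x, ...) {
  cat(sprintf("<module_stack> %d modules, gains %s\n", length(x$modules),
              paste(x$gains, collapse = ", ")))
  invisible(x)
}

#' Run the whole stack over a trajectory (pure path integration)
#'
#' Every module consumes the same velocity stream; per-module position
#' estimates integrate `gamma * delta-bump` from the trajectory start.
#'
#' @param stack A [module_stack()].
#' @param traj A trajectory data frame.
#' @param record_activity Keep full activity traces?
#' @return List with per-module `centers`, `deltas` (torus bump
#'   displacements), `max_activity` (steps x modules), `positions` (list of
#'   steps x 2 pure-integration estimates), and optionally `activity`.
#' @export
stack_run <- function(stack, traj, record_activity = FALSE) {
  v <- trajectory_velocities(traj)
  n <- nrow(traj)
  nm <- length(stack$modules)
  centers <- deltas <- positions <- activity <- vector("list", nm)
  maxA <- matrix(0, n, nm)
  start <- c(traj$x[1], traj$y[1])
  for (m in seq_len(nm)) {
    mod <- stack$modules[[m]]
    r <- can_run(mod, v[, 1], v[, 2], record_activity = record_activity)
    cen <- r$centers
    d <- rbind(c(0, 0),
               torus_displacement(cen[-1, , drop = FALSE],
                                  cen[-n, , drop = FALSE], mod$coords$Py))
    pos <- cbind(start[1] + cumsum(mod$gamma * d[, 1]),
                 start[2] + cumsum(mod$gamma * d[, 2]))
    centers[[m]] <- cen; deltas[[m]] <- d; positions[[m]] <- pos
    maxA[, m] <- r$max_activity
    if (record_activity) activity[[m]] <- r$activity
  }
  out <- list(centers = centers, deltas = deltas, positions = positions,
              max_activity = maxA)
  if (record_activity) out$activity <- activity
  out
}
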