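#' Square exploration arena with perimeter landmarks
#'
#' Defines the simulated environment: a square arena of side `side_length`
#' (arbitrary units, a.u.) whose boundary walls carry visually distinct
#' landmarks.  Landmarks are placed evenly just beyond the four walls; each has
#' identity-linked visual features (solidity and axis orientation) that do not
#' change with viewpoint, and a position from which pose-linked features
#' (apparent area, image centroid) are derived when the landmark is in view.
#'
#' @param side_length Arena side L in a.u. (default 100).
#' @param n_landmarks Number of landmarks spread around the perimeter.
#' @param fov Horizontal field of view in radians used for landmark visibility.
#' @param wall_offset Distance beyond the walls at which landmarks stand.
#' @param seed Integer seed fixing the landmark identity features.
#' @return An object of class `arena`: list with elements `L`, `fov` and
#'   `landmarks` (data frame with `id`, `x`, `y`, `solidity`, `orientation`).
#' @export
arena <- function(side_length = 100, n_landmarks = 40, fov = pi / 2,
                  wall_offset = 10, seed = 1L) {
  stopifnot(side_length > 0, n_landmarks >= 1, fov > 0)
  L <- side_length
  per_side <- ceiling(n_landmarks / 4)
  u <- (seq_len(per_side) - 0.5) / per_side * L
  pos <- rbind(
    cbind(u, -wall_offset),       # south
    cbind(L + wall_offset, u),    # east
    cbind(rev(u), L + wall_offset), # north
    cbind(-wall_offset, rev(u))   # west
  )[seq_len(n_landmarks), , drop = FALSE]
  feats <- with_seed(seed, {
    data.frame(solidity = stats::runif(n_landmarks, 0.3, 1),
               orientation = stats::runif(n_landmarks, 0, pi))
  })
  structure(list(
    L = L, fov = fov,
    landmarks = data.frame(id = seq_len(n_landmarks),
                           x = pos[, 1], y = pos[, 2],
                           solidity = feats$solidity,
                           orientation = feats$orientation)
  ), class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> side %g a.u., %d landmarks, FOV %.0f deg\n",
              x$L, nrow(x$landmarks), x$fov * 180 / pi))
  invisible(x)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Generate a synthetic exploration trajectory
#'
#' Bounded correlated random walk inside the arena, in one of two styles seen
#' in open-field rodent exploration: `"center_biased"` (S1-like; paths
#' unevenly distributed around the middle of the arena) or `"wall_following"`
#' (S2-like; the walker holds a band near the walls, with occasional crossings
#' so the whole arena is still covered over long runs).  The walk starts at
#' the arena center with a random orientation; per-step displacement is capped
#' by `speed_max`.
#'
#' @param style `"center_biased"` or `"wall_following"`.
#' @param n_steps Number of steps (>= 1).
#' @param arena An [arena()] object.
#' @param seed Integer seed; fixes all randomness of the walk.
#' @param speed_max Maximum per-step displacement (a.u./step).
#' @return A `trajectory` data frame with columns `t` (0-based step index),
#'   `x`, `y` (a.u.) and `heading` (radians).
#' @export
generate_trajectory <- function(style = c("center_biased", "wall_following"),
                                n_steps, arena, seed = 1L, speed_max = 1.5) {
  style <- match.arg(style)
  if (!is.numeric(n_steps) || n_steps < 1)
    stop("n_steps must be a positive integer")
  n_steps <- as.integer(n_steps)
  L <- arena$L
  x <- y <- hd <- numeric(n_steps)
  with_seed(seed, {
    px <- L / 2; py <- L / 2
    head <- stats::runif(1, -pi, pi)
    x[1] <- px; y[1] <- py; hd[1] <- head
    band <- 10                       # wall-following band width (a.u.)
    crossing <- FALSE; cross_target <- c(0, 0)
    tang_sign <- sample(c(-1, 1), 1) # persistent wall-following direction
    for (t in seq_len(n_steps - 1L)) {
      turn <- stats::rnorm(1, 0, 0.35)
      if (style == "center_biased") {
        # weak pull towards the center, strong when close to a wall
        bc <- atan2(L / 2 - py, L / 2 - px)
        dwall <- min(px, py, L - px, L - py)
        k <- if (dwall < 6) 0.35 else 0.01
        turn <- turn + k * wrap_angle(bc - head)
      } else {
        dwall <- min(px, py, L - px, L - py)
        if (!crossing && stats::runif(1) < 0.004) {
          crossing <- TRUE
          cross_target <- stats::runif(2, 0.2 * L, 0.8 * L)
        }
        if (crossing) {
          bt <- atan2(cross_target[2] - py, cross_target[1] - px)
          turn <- turn + 0.4 * wrap_angle(bt - head)
          if (sqrt((px - cross_target[1])^2 + (py - cross_target[2])^2) < 5)
            crossing <- FALSE
        } else if (dwall > band) {
          # steer towards the nearest wall
          walls <- c(px, py, L - px, L - py)
          wdir <- c(pi, -pi / 2, 0, pi / 2)[which.min(walls)]
          turn <- turn + 0.35 * wrap_angle(wdir - head)
        } else {
          # follow the wall tangentially; which.min wall: 1 west, 2 south,
          # 3 east, 4 north -> tangent is vertical for E/W, horizontal for N/S
          wi <- which.min(c(px, py, L - px, L - py))
          tang <- if (wi %in% c(1, 3)) tang_sign * pi / 2
                  else if (tang_sign > 0) 0 else pi
          turn <- turn + 0.3 * wrap_angle(tang - head)
          if (stats::runif(1) < 0.002) tang_sign <- -tang_sign
        }
      }
      head <- wrap_angle(head + turn)
      sp <- stats::runif(1, 0.15, 1) * speed_max
      nx <- px + sp * cos(head); ny <- py + sp * sin(head)
      # reflect off the walls
      if (nx < 0) { nx <- -nx; head <- wrap_angle(pi - head) }
      if (nx > L) { nx <- 2 * L - nx; head <- wrap_angle(pi - head) }
      if (ny < 0) { ny <- -ny; head <- wrap_angle(-head) }
      if (ny > L) { ny <- 2 * L - ny; head <- wrap_angle(-head) }
      px <- nx; py <- ny
      x[t + 1] <- px; y[t + 1] <- py; hd[t + 1] <- head
    }
  })
  traj <- data.frame(t = 0:(n_steps - 1), x = x, y = y, heading = hd)
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "L") <- L
  traj
}

#' Per-step planar velocities of a trajectory
#'
#' `v(t) = pos(t) - pos(t-1)`; the first step has zero velocity.
#' @param traj A trajectory data frame.
#' @return n x 2 matrix of velocities (a.u./step).
#' @export
trajectory_velocities <- function(traj) {
  n <- nrow(traj)
  vx <- c(0, diff(traj$x)); vy <- c(0, diff(traj$y))
  cbind(vx = vx, vy = vy)
}

#' Read / write a trajectory CSV (`t,x,y,heading`)
#' @param path File path.
#' @param L Arena side length to attach (default: max coordinate rounded up).
#' @return A `trajectory` data frame.
#' @export
read_trajectory_csv <- function(path, L = NULL) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "heading")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns t,x,y,heading")
  df <- df[need]
  class(df) <- c("trajectory", "data.frame")
  attr(df, "L") <- if (is.null(L)) ceiling(max(df$x, df$y)) else L
  df
}

#' @rdname read_trajectory_csv
#' @param traj Trajectory to write.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[c("t", "x", "y", "heading")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Noisy proximity reading at a position
#'
#' The three proximity sensors report the animal's position along the three
#' main axes (left-right, back-front, down-up); the down-up component is
#' constant.  Multiplicative sensory noise is applied per component:
#' `X' = X * (1 + alpha * eta)`, `eta ~ U(-1, 1)` i.i.d.
#'
#' Uses the current R random stream; seed with [set.seed()] (or let the
#' simulation runner manage streams).
#'
#' @param pos Length-2 position `(x, y)` inside the arena.
#' @param arena An [arena()] object.
#' @param alpha Sensory error rate (default 0.1).
#' @param z_const Constant down-up component (default L/2).
#' @return List with `X_true` and `X_noisy` (length-3 numeric vectors).
#' @export
sense_proximity <- function(pos, arena, alpha = 0.1, z_const = arena$L / 2) {
  L <- arena$L
  if (pos[1] < 0 || pos[1] > L || pos[2] < 0 || pos[2] > L)
    stop("position outside the arena")
  X <- c(pos[1], pos[2], z_const)
  eta <- stats::runif(3, -1, 1)
  list(X_true = X, X_noisy = X * (1 + alpha * eta))
}

#' Parametric visual blob features for the landmarks in view
#'
#' Stand-in for image-based blob detection: every landmark inside the forward
#' field of view yields one blob whose identity-linked features (solidity,
#' orientation) depend only on the landmark, and whose pose-linked features
#' depend on the relative position: apparent `area` falls off as 1/distance^2
#' (capped at 1) and the image `centroid` follows the bearing (horizontal `cu`)
#' and distance (vertical `cv`).  Deterministic given `(pos, heading)`.
#'
#' @param pos Length-2 position inside the arena.
#' @param heading Heading in radians.
#' @param arena An [arena()] object.
#' @param area_scale Area at distance 20 a.u. is `area_scale/400` (default 1).
#' @return Data frame of blobs: `id, area, orientation, solidity, cu, cv,
#'   dist, bearing` (possibly 0 rows).
#' @export
generate_blobs <- function(pos, heading, arena, area_scale = 400) {
  L <- arena$L
  if (pos[1] < 0 || pos[1] > L || pos[2] < 0 || pos[2] > L)
    stop("position outside the arena")
  lm <- arena$landmarks
  dx <- lm$x - pos[1]; dy <- lm$y - pos[2]
  d <- sqrt(dx^2 + dy^2)
  bear <- wrap_angle(atan2(dy, dx) - heading)
  vis <- abs(bear) <= arena$fov / 2 & d > 1e-9
  if (!any(vis)) {
    return(data.frame(id = integer(0), area = numeric(0),
                      orientation = numeric(0), solidity = numeric(0),
                      cu = numeric(0), cv = numeric(0),
                      dist = numeric(0), bearing = numeric(0)))
  }
  d <- d[vis]; bear <- bear[vis]
  data.frame(id = lm$id[vis],
             area = pmin(1, area_scale / d^2),
             orientation = lm$orientation[vis],
             solidity = lm$solidity[vis],
             cu = 0.5 + bear / arena$fov,
             cv = 0.5 + atan(10 / d) / pi,
             dist = d, bearing = bear)
}
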