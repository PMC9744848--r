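#' Grid-to-place connection matrix
#'
#' Place-cell x module weight matrix: each module contributes a Gaussian
#' column over a one-dimensional place-cell index coordinate rescaled to
#' `[0, 10]`, with the five Gaussian centers spread evenly over that range.
#'
#' @param n_cells Number of place cells.
#' @param n_modules Number of grid modules (default 5).
#' @param range Index coordinate range (default `c(0, 10)`).
#' @param width Gaussian width (default 2.5).
#' @return `n_cells x n_modules` nonnegative matrix.
#' @export
gp_weight_matrix <- function(n_cells, n_modules = 5, range = c(0, 10),
                             width = 2.5) {
  s <- seq(range[1], range[2], length.out = n_cells)
  mu <- seq(range[1], range[2], length.out = n_modules)
  outer(s, mu, function(a, b) exp(-(a - b)^2 / (2 * width^2)))
}

#' Grid-module drive onto the place cells
#'
#' The maximum grid activity of each module is multiplied by the grid-to-place
#' weight matrix and averaged across modules:
#' `drive_j = mean_m(max_i A_i^(m) * W_GP[j, m])`.  Cells with drive above the
#' threshold (1.1 a.u.) receive "enough input from grid modules".
#'
#' @param max_activity Length-`n_modules` per-module maximum activity.
#' @param W_GP Matrix from [gp_weight_matrix()].
#' @return Per-cell drive.
#' @export
grid_drive <- function(max_activity, W_GP) {
  as.numeric(W_GP %*% max_activity) / ncol(W_GP)
}

#' Place-field emergence gate
#'
#' A place field can be registered at the current position only when three
#' conditions hold simultaneously: (i) the cell's H-H unit fired this step,
#' (ii) the grid drive exceeds `drive_thr` (1.1 a.u.), and (iii) the cell's
#' preferred features match the visual scene (`A > A_thr`).
#'
#' @param fired Logical (per cell).
#' @param drive Grid drive (per cell).
#' @param A Feature-match activation (per cell).
#' @param A_thr Feature-match threshold.
#' @param drive_thr Grid-input threshold (default 1.1).
#' @return Logical vector.
#' @export
emergence_gate <- function(fired, drive, A, A_thr, drive_thr = 1.1) {
  fired & drive > drive_thr & A > A_thr
}

#' Cross-module position-estimate uncertainty
#'
#' `E = sqrt(sd(pos_x)^2 + sd(pos_y)^2)` across the module estimates (sample,
#' n-1, standard deviation).  Zero iff all modules agree exactly; values above
#' the threshold (1.5 a.u.) mark the current position as "uncertain".
#'
#' @param pos_m Modules x 2 matrix of position estimates (>= 2 rows).
#' @return Nonnegative scalar.
#' @export
estimate_error <- function(pos_m) {
  pos_m <- rbind(pos_m)
  if (nrow(pos_m) < 2) stop("estimate_error needs >= 2 module estimates")
  sqrt(stats::sd(pos_m[, 1])^2 + stats::sd(pos_m[, 2])^2)
}

#' Correct the module estimates from the nearest place-field center
#'
#' If the nearest field center to the animal's current position lies within
#' the snap radius (2.5 a.u.), every module's position estimate is reset to
#' that center; otherwise the estimates are unchanged.  Equidistant centers
#' break ties towards the lowest index.
#'
#' @param pos_m Modules x 2 estimates.
#' @param centers n x 2 field centers (possibly 0 rows, NA rows skipped).
#' @param pos_true Current true position.
#' @param snap_radius Correction radius (default 2.5).
#' @return List: `pos_m` (possibly corrected), `event` (NULL or list with
#'   `center`, `index`, `distance`).
#' @export
correct_position <- function(pos_m, centers, pos_true, snap_radius = 2.5) {
  pos_m <- rbind(pos_m)
  centers <- rbind(centers)
  if (is.null(centers) || nrow(centers) == 0)
    return(list(pos_m = pos_m, event = NULL))
  ok <- which(is.finite(centers[, 1]) & is.finite(centers[, 2]))
  if (length(ok) == 0) return(list(pos_m = pos_m, event = NULL))
  d <- sqrt((centers[ok, 1] - pos_true[1])^2 +
              (centers[ok, 2] - pos_true[2])^2)
  i <- which.min(d)           # first minimum = lowest index on ties
  if (d[i] > snap_radius) return(list(pos_m = pos_m, event = NULL))
  ctr <- centers[ok[i], ]
  pos_m[, 1] <- ctr[1]; pos_m[, 2] <- ctr[2]
  list(pos_m = pos_m,
       event = list(center = ctr, index = ok[i], distance = d[i]))
}

#' Plasticity of the grid-to-place weights
#'
#' For the active place cells, `W_GP <- W_GP + mu (X' - W_GP)` towards the
#' noisy sensor signal; inactive rows are untouched.  The sensor vector is
#' broadcast as its scalar mean by default (`per_component = TRUE` uses the
#' first `n_modules` components instead).
#'
#' @param W_GP Current matrix.
#' @param X_noisy Noisy sensor vector.
#' @param active Indices (or logical) of active cells.
#' @param mu Learning rate (default 0.001).
#' @param per_component Broadcast variant (default FALSE = scalar mean).
#' @return Updated matrix.
#' @export
update_gp_weights <- function(W_GP, X_noisy, active, mu = 0.001,
                              per_component = FALSE) {
  if (length(active) == 0) return(W_GP)
  x <- if (per_component)
    matrix(rep_len(X_noisy, ncol(W_GP)), nrow = length(active),
           ncol = ncol(W_GP), byrow = TRUE)
  else mean(X_noisy)
  W_GP[active, ] <- W_GP[active, , drop = FALSE] +
    mu * (x - W_GP[active, , drop = FALSE])
  W_GP
}

#' Run the full coupled place-grid simulation
#'
#' One pass over a trajectory: proximity sensing, place-network dynamics
#' (H-H firing, competitive weight learning, feature matching and winner
#' adaptation), the five-module CAN path integration, cross-module
#' uncertainty, place-field emergence and (optionally) place-field-based
#' correction of the position estimates.  Grid-cell firing itself is never
#' altered by the place input; emerging fields affect only the position
#' estimates, so the CAN activity is computed in a single pass up front.
#'
#' @param config An [experiment_config()].
#' @param stack Optional pre-built [module_stack()] (reused across arms so
#'   that ON/OFF comparisons share identical grid activity).
#' @param traj Optional pre-built trajectory.
#' @param record_activity Keep CAN activity traces (needed for rate maps).
#' @return An object of class `placegrid_run`; see Details.
#'
#' @details The result contains: `trajectory`; `estimates` (list of steps x 2
#' per-module corrected estimates); `pure_estimates` (no corrections);
#' `E_error`, `uncertain`, `module_error` (steps x modules Euclidean error);
#' `fields` (per-cell field table), `field_centers`; `decoded` (steps x 3:
#' loc and err_norm); `entropy` (per-step entropy suite time series);
#' `corrections` (event log); `n_fields` series; `config`.
#' @export
run_simulation <- function(config, stack = NULL, traj = NULL,
                           record_activity = FALSE) {
  cf <- config
  warm <- if (is.null(cf$warmup_steps)) 0L else as.integer(cf$warmup_steps)
  n_total <- as.integer(cf$n_steps) + warm
  if (n_total == 0) return(empty_run(cf))
  ar <- arena(side_length = cf$L, n_landmarks = cf$n_landmarks,
              fov = cf$fov, seed = derive_seed(cf$seed, "landmarks"))
  if (is.null(traj))
    traj <- generate_trajectory(cf$style, n_total, ar,
                                seed = derive_seed(cf$seed, "trajectory"),
                                speed_max = cf$speed_max)
  if (nrow(traj) != n_total)
    stop("supplied trajectory length must equal warmup_steps + n_steps")
  n <- nrow(traj)
  if (is.null(stack))
    stack <- module_stack(gains = cf$gains, seed = cf$seed,
                          spacing_factor = cf$spacing_factor,
                          I_a = cf$I_a, sigma_w = cf$sigma_w,
                          T_shift = cf$T_shift, tau = cf$tau, beta = cf$beta)
  gr <- stack_run(stack, traj, record_activity = record_activity)
  nm <- length(stack$modules)
  gammas <- vapply(stack$modules, function(m) m$gamma, 0)

  net <- place_network(cf$n_cells, cf$n_sensors,
                       seed = derive_seed(cf$seed, "place_init"),
                       R_m = cf$R_m, P_thr = cf$P_thr, mu = cf$mu)
  W_GP <- gp_weight_matrix(cf$n_cells, nm, width = cf$gp_width)
  eta <- with_seed(derive_seed(cf$seed, "noise"),
                   matrix(stats::runif(n * cf$n_sensors, -1, 1), n,
                          cf$n_sensors))

  fixed_centers <- NULL
  if (cf$field_mode == "fixed") {
    fixed_centers <- with_seed(derive_seed(cf$seed, "fixed_fields"),
                               matrix(stats::runif(2 * cf$n_fixed_fields, 0,
                                                   cf$L),
                                      cf$n_fixed_fields, 2))
  }

  # per-cell field accumulators
  nc <- cf$n_cells
  has_field <- logical(nc)
  emergence_step <- rep(NA_integer_, nc)
  sumP <- sumPx <- sumPy <- numeric(nc)
  peakP <- rep(-Inf, nc); peakx <- peaky <- rep(NA_real_, nc)
  members <- vector("list", nc)
  spike_counts <- numeric(nc)

  pos_m <- matrix(rep(c(traj$x[1], traj$y[1]), each = nm), nm, 2)
  est <- lapply(seq_len(nm), function(m) matrix(NA_real_, n, 2))
  E_series <- numeric(n); uncertain <- logical(n)
  nf_series <- integer(n)
  dec <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("loc_x", "loc_y",
                                                        "err_norm")))
  ent <- matrix(NA_real_, n, 7,
                dimnames = list(NULL, c("H", "S", "Z", "r", "R", "I", "n")))
  corrections <- list(); n_corr <- 0
  peak_shift <- rep(NA_real_, n)   # mean per-step place-field peak shift
  # fixed (preassigned) fields cannot be influenced by place activity, so the
  # place-network dynamics are skipped entirely in that mode
  do_place <- cf$field_mode == "emergent"

  for (t in seq_len(n)) {
    pos <- c(traj$x[t], traj$y[t])
    X_true <- c(pos, cf$L / 2)
    X_noisy <- X_true * (1 + cf$alpha * eta[t, ])

    # place network --------------------------------------------------------
    if (do_place) {
    P <- firing_power(net, X_noisy, cf$L)
    # every unit receives the reference current I; cells spike on their own
    # H-H rhythm (phases decorrelated by the random initial potentials)
    hh <- hh_integrate(net$hh, cf$I_max, n_sub = cf$hh_substeps,
                       dt = cf$hh_dt)
    net$hh <- hh[c("V", "m", "h", "n")]
    fired <- hh$spikes > 0

    blobs <- generate_blobs(pos, traj$heading[t], ar)
    act <- place_activation(blobs, net, sigma_f = cf$sigma_f)
    A <- act$A
    if (nrow(blobs) >= 2 && max(A) > 0) {
      w <- which.max(A)
      xb1 <- blob_feature_vector(blobs, act$best1[w])
      xb2 <- blob_feature_vector(blobs, act$best2[w])
      net$M1[w, ] <- adapt_feature_centers(net$M1[w, , drop = FALSE],
                                           xb1, cf$alpha_adapt)
      net$M2[w, ] <- adapt_feature_centers(net$M2[w, , drop = FALSE],
                                           xb2, cf$alpha_adapt)
    }
    responding <- which(P > net$P_thr)
    net <- competitive_update(net, X_noisy, cf$L, responding)
    # field membership and the center integrals run over ALL supra-threshold
    # steps (the field is the set of locations with firing power above
    # threshold; its center is the power-weighted average over the whole run)
    if (length(responding) > 0) {
      sumP[responding] <- sumP[responding] + P[responding]
      sumPx[responding] <- sumPx[responding] + P[responding] * X_noisy[1]
      sumPy[responding] <- sumPy[responding] + P[responding] * X_noisy[2]
      key <- floor(pos[1]) + 128 * floor(pos[2])
      for (j in responding) members[[j]] <- c(members[[j]], key)
      better <- responding[P[responding] > peakP[responding]]
      if (length(better) > 0) {
        pk0x <- peakx[better]; pk0y <- peaky[better]
        peakP[better] <- P[better]
        peakx[better] <- pos[1]; peaky[better] <- pos[2]
        sel <- is.finite(pk0x) & has_field[better]
        if (any(sel))
          peak_shift[t] <- mean(sqrt((pos[1] - pk0x[sel])^2 +
                                       (pos[2] - pk0y[sel])^2))
      }
    }
    }

    # grid stack: advance estimates ---------------------------------------
    for (m in seq_len(nm))
      pos_m[m, ] <- pos_m[m, ] + gammas[m] * gr$deltas[[m]][t, ]
    E <- estimate_error(pos_m)
    E_series[t] <- E
    uncertain[t] <- E > cf$E_thr

    # emergence -------------------------------------------------------------
    if (do_place) {
      drive <- grid_drive(gr$max_activity[t, ], W_GP)
      gate <- emergence_gate(fired, drive, A, cf$A_thr, cf$drive_thr)
      if (uncertain[t] && any(gate)) {
        g <- which(gate)
        newf <- g[!has_field[g]]
        has_field[g] <- TRUE
        emergence_step[newf] <- t
        # make sure a brand-new field has a defined center even if the cell
        # has not yet crossed the firing-power threshold anywhere
        fresh <- newf[sumP[newf] <= 0]
        if (length(fresh) > 0) {
          sumP[fresh] <- sumP[fresh] + P[fresh]
          sumPx[fresh] <- sumPx[fresh] + P[fresh] * X_noisy[1]
          sumPy[fresh] <- sumPy[fresh] + P[fresh] * X_noisy[2]
          key <- floor(pos[1]) + 128 * floor(pos[2])
          for (j in fresh) members[[j]] <- c(members[[j]], key)
        }
      }
    }
    nf_series[t] <- if (do_place) sum(has_field) else cf$n_fixed_fields

    # correction ------------------------------------------------------------
    centers <- if (cf$field_mode == "fixed") fixed_centers
               else if (any(has_field))
                 cbind(sumPx[has_field] / sumP[has_field],
                       sumPy[has_field] / sumP[has_field])
               else NULL
    if (isTRUE(cf$place_input) && uncertain[t] && !is.null(centers)) {
      cr <- correct_position(pos_m, centers, pos, cf$snap_radius)
      if (!is.null(cr$event)) {
        pos_m <- cr$pos_m
        n_corr <- n_corr + 1
        corrections[[n_corr]] <- data.frame(t = t, center_x = cr$event$center[1],
                                            center_y = cr$event$center[2],
                                            distance = cr$event$distance)
      }
    }
    for (m in seq_len(nm)) est[[m]][t, ] <- pos_m[m, ]

    # plasticity of grid-to-place weights -----------------------------------
    if (do_place) {
    W_GP <- update_gp_weights(W_GP, X_noisy, responding, mu = cf$mu_gp,
                              per_component = cf$gp_per_component)

    # decoding + entropy -----------------------------------------------------
    spike_counts <- spike_counts + hh$spikes
    if (any(has_field)) {
      cen_all <- matrix(NA_real_, nc, 2)
      cen_all[has_field, ] <- cbind(sumPx[has_field] / sumP[has_field],
                                    sumPy[has_field] / sumP[has_field])
      d <- decode_location(P, cen_all, pos, cf$L, net$P_thr)
      dec[t, ] <- c(d$loc, d$err_norm)
      cnt <- spike_counts[has_field]
      if (sum(cnt) > 0) {
        p <- cnt / sum(cnt)
        es <- entropy_suite(p, dx = cf$field_size)
        ent[t, ] <- c(es$H, es$S, es$Z, es$r, es$R, es$I, length(p))
      }
    } else {
      dec[t, ] <- c(NA, NA, 1)
    }
    }
  }

  # measured window: drop the warmup prefix and re-anchor the uncorrected
  # (pure path-integration) estimates at the true window start
  win <- (warm + 1L):n
  truth <- cbind(traj$x, traj$y)[win, , drop = FALSE]
  est <- lapply(est, function(e) e[win, , drop = FALSE])
  pure <- lapply(seq_len(nm), function(m) {
    d <- gr$deltas[[m]][win, , drop = FALSE]
    d[1, ] <- 0
    cbind(truth[1, 1] + cumsum(gammas[m] * d[, 1]),
          truth[1, 2] + cumsum(gammas[m] * d[, 2]))
  })
  traj_out <- traj[win, , drop = FALSE]
  traj_out$t <- seq_len(length(win)) - 1L
  rownames(traj_out) <- NULL
  class(traj_out) <- c("trajectory", "data.frame")
  attr(traj_out, "L") <- cf$L
  mod_err <- vapply(seq_len(nm), function(m)
    sqrt(rowSums((est[[m]] - truth)^2)), numeric(length(win)))

  fields <- NULL
  if (cf$field_mode == "emergent" && any(has_field)) {
    idx <- which(has_field)
    fields <- data.frame(cell_id = idx, emergence_step = emergence_step[idx],
                         center_x = sumPx[idx] / sumP[idx],
                         center_y = sumPy[idx] / sumP[idx],
                         peak_x = peakx[idx], peak_y = peaky[idx],
                         n_member_locations = vapply(members[idx], function(k)
                           length(unique(k)), 0L))
  }

  corr <- if (n_corr > 0) do.call(rbind, corrections) else
    data.frame(t = integer(0), center_x = numeric(0),
               center_y = numeric(0), distance = numeric(0))
  corr <- corr[corr$t > warm, , drop = FALSE]
  corr$t <- corr$t - warm
  if (!is.null(fields)) fields$emergence_step <- fields$emergence_step - warm

  structure(list(
    trajectory = traj_out, estimates = est, pure_estimates = pure,
    E_error = E_series[win], uncertain = uncertain[win],
    module_error = mod_err, fields = fields,
    field_centers = if (cf$field_mode == "fixed") fixed_centers else
      if (!is.null(fields)) cbind(fields$center_x, fields$center_y) else NULL,
    decoded = dec[win, , drop = FALSE], entropy = ent[win, , drop = FALSE],
    n_fields = nf_series[win], corrections = corr,
    peak_shift = peak_shift[win],
    max_activity = gr$max_activity[win, , drop = FALSE],
    grid = gr, stack = stack, config = cf
  ), class = "placegrid_run")
}

#' @export
print.placegrid_run <- function(x, ...) {
  cat(sprintf(paste0("<placegrid_run> %d steps (%s), place input %s, %d ",
                     "fields, %d corrections\n"),
              nrow(x$trajectory), x$config$style,
              if (isTRUE(x$config$place_input)) "on" else "off",
              max(x$n_fields), nrow(x$corrections)))
  invisible(x)
}


# degenerate zero-step run: empty, schema-compatible outputs
empty_run <- function(cf) {
  emptytraj <- data.frame(t = integer(0), x = numeric(0), y = numeric(0),
                          heading = numeric(0))
  class(emptytraj) <- c("trajectory", "data.frame")
  attr(emptytraj, "L") <- cf$L
  nm <- length(cf$gains)
  structure(list(
    trajectory = emptytraj,
    estimates = replicate(nm, matrix(numeric(0), 0, 2), simplify = FALSE),
    pure_estimates = replicate(nm, matrix(numeric(0), 0, 2),
                               simplify = FALSE),
    E_error = numeric(0), uncertain = logical(0),
    module_error = matrix(numeric(0), 0, nm), fields = NULL,
    field_centers = NULL,
    decoded = matrix(numeric(0), 0, 3,
                     dimnames = list(NULL, c("loc_x", "loc_y", "err_norm"))),
    entropy = matrix(numeric(0), 0, 7,
                     dimnames = list(NULL, c("H", "S", "Z", "r", "R", "I",
                                             "n"))),
    n_fields = integer(0),
    corrections = data.frame(t = integer(0), center_x = numeric(0),
                             center_y = numeric(0), distance = numeric(0)),
    peak_shift = numeric(0), max_activity = matrix(numeric(0), 0, nm),
    grid = NULL, stack = NULL, config = cf
  ), class = "placegrid_run")
}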