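#' Experiment configuration
#'
#' Collects every tunable of the simulator with defaults at the model's
#' reference values: 2000 place cells, 3 proximity sensors, sensory error
#' rate 0.1, learning rates 0.001, maximum firing rate 20 Hz, firing
#' threshold 0.3, 10,000 simulation steps, CAN stabilisation 0.95, gains
#' 0.04-0.08, uncertainty threshold 1.5 a.u., snap radius 2.5 a.u., grid
#' drive threshold 1.1 a.u.
#'
#' @param style Trajectory style (`"center_biased"` = S1, `"wall_following"`
#'   = S2) .
#' @param n_steps Number of measured simulation steps.
#' @param warmup_steps Exploration steps run before the measured window
#'   (place-field formation continues throughout; outputs cover only the
#'   window).  Default 0; the error-reduction recipe uses 2000, the
#'   field-plateau time.
#' @param seed Master seed; per-component streams are derived from it.
#' @param L Arena side (a.u.).
#' @param n_landmarks,fov,speed_max Arena / trajectory generator settings.
#' @param alpha Sensory error rate.
#' @param n_cells,n_sensors Place network size.
#' @param R_m,P_thr,mu Place firing/learning parameters.
#' @param sigma_f Feature-match sensitivity.
#' @param A_thr Feature-match activation threshold for the emergence gate.
#' @param alpha_adapt Winner feature-adaptation rate.
#' @param hh_substeps,hh_dt,I_max H-H sub-integration per step and drive scale.
#' @param gains,I_a,sigma_w,T_shift,tau,beta,spacing_factor CAN parameters.
#' @param E_thr,snap_radius,drive_thr,mu_gp,gp_width,gp_per_component
#'   Coupling parameters.
#' @param place_input Place-field correction switch.
#' @param field_mode `"emergent"` or `"fixed"` (randomly placed fields).
#' @param n_fixed_fields Number of fixed random fields when
#'   `field_mode = "fixed"`.
#' @param field_size Event size `dx` for the entropy suite (a.u.).
#' @return Validated list of class `experiment_config`.
#' @export
experiment_config <- function(style = "center_biased", n_steps = 10000,
                              warmup_steps = 0,
                              seed = 1L, L = 100, n_landmarks = 40,
                              fov = pi / 2, speed_max = 1.5, alpha = 0.1,
                              n_cells = 2000, n_sensors = 3, R_m = 20,
                              P_thr = 0.3, mu = 0.001, sigma_f = 0.5,
                              A_thr = 0.1, alpha_adapt = 0.5,
                              hh_substeps = 100, hh_dt = 0.01, I_max = 10,
                              gains = c(0.04, 0.05, 0.06, 0.07, 0.08),
                              I_a = 0.3, sigma_w = 0.24, T_shift = 0.05,
                              tau = 0.95, beta = 0, spacing_factor = 0.95,
                              E_thr = 1.5, snap_radius = 2.5,
                              drive_thr = 1.1, mu_gp = 0.001, gp_width = 2.5,
                              gp_per_component = FALSE, place_input = TRUE,
                              field_mode = c("emergent", "fixed"),
                              n_fixed_fields = 20, field_size = 20) {
  cf <- as.list(environment())
  cf$field_mode <- match.arg(field_mode)
  cf$style <- match.arg(style, c("center_biased", "wall_following"))
  num_pos <- c("L", "speed_max", "R_m", "P_thr", "mu", "sigma_f",
               "alpha_adapt", "hh_substeps", "hh_dt", "I_a", "sigma_w",
               "tau", "E_thr", "snap_radius", "drive_thr", "mu_gp",
               "gp_width", "field_size")
  for (f in num_pos)
    if (!is.numeric(cf[[f]]) || length(cf[[f]]) != 1 || cf[[f]] <= 0)
      stop(sprintf("config field '%s' must be a positive number", f))
  if (!is.numeric(cf$n_steps) || cf$n_steps < 0)
    stop("config field 'n_steps' must be a nonnegative integer")
  if (!is.numeric(cf$warmup_steps) || cf$warmup_steps < 0)
    stop("config field 'warmup_steps' must be a nonnegative integer")
  if (cf$tau >= 1) stop("config field 'tau' must be in [0, 1)")
  if (length(cf$gains) < 1 || any(cf$gains <= 0))
    stop("config field 'gains' must be positive")
  if (cf$field_mode == "fixed" &&
      (!is.numeric(cf$n_fixed_fields) || cf$n_fixed_fields < 1))
    stop("config field 'n_fixed_fields' must be a positive integer")
  structure(cf, class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose keys are
#'   [experiment_config()] arguments.
#' @param ... Overrides.
#' @return An `experiment_config`.
#' @export
read_config <- function(path, ...) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- utils::modifyList(vals, list(...))
  do.call(experiment_config, vals)
}

#' Run an experiment and optionally write its outputs
#'
#' Executes [run_simulation()] under the configuration and, when `out_dir`
#' is given, writes the standard CSV outputs and a JSON manifest:
#' `trajectory.csv`, `module_estimates.csv`, `decoded.csv`,
#' `place_fields.csv`, `corrections.csv`, `entropy_timeseries.csv`,
#' `errors.csv`, `manifest.json`.  Outputs are a pure function of
#' `(config, seed)`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing) or `NULL`.
#' @param ... Passed to [run_simulation()].
#' @return The `placegrid_run` (invisibly when writing).
#' @export
run_experiment <- function(config, out_dir = NULL, ...) {
  run <- run_simulation(config, ...)
  if (is.null(out_dir)) return(run)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(as.data.frame(run$trajectory), "trajectory.csv")
  nm <- length(run$estimates)
  est <- do.call(rbind, lapply(seq_len(nm), function(m)
    data.frame(t = run$trajectory$t, module = rep(m, nrow(run$trajectory)),
               pos_x = run$estimates[[m]][, 1],
               pos_y = run$estimates[[m]][, 2],
               error = run$module_error[, m])))
  wcsv(est, "module_estimates.csv")
  wcsv(data.frame(t = run$trajectory$t, run$decoded), "decoded.csv")
  if (!is.null(run$fields)) wcsv(run$fields, "place_fields.csv")
  wcsv(run$corrections, "corrections.csv")
  wcsv(data.frame(t = run$trajectory$t, n_fields = run$n_fields,
                  run$entropy), "entropy_timeseries.csv")
  wcsv(data.frame(t = run$trajectory$t, E_error = run$E_error,
                  uncertain = run$uncertain), "errors.csv")
  manifest <- list(package = "placegrid",
                   version = as.character(utils::packageVersion("placegrid")),
                   seed = config$seed,
                   config = unclass(config)[order(names(unclass(config)))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' Canned experiment recipes
#'
#' Reproduces the simulator's standard figure-level protocols:
#' \describe{
#'   \item{`error_reduction`}{place input ON vs OFF on identical
#'     trajectories (default 1000 steps).}
#'   \item{`field_density`}{20 vs 200 fixed random place fields, same
#'     trajectories.}
#'   \item{`gridness`}{center-biased vs wall-following mean gridness from the
#'     isolated grid network.}
#'   \item{`entropy`}{a full emergent run and its field-count/entropy
#'     dynamics.}
#' }
#'
#' @param name Recipe name (see above).
#' @param seeds Integer vector of seeds (default 1:5; the `entropy` recipe
#'   defaults to 1:3, one full-length coupled run per seed).
#' @param n_steps Steps per run (default: 1000 for the comparisons, 10000
#'   for gridness/entropy).
#' @param ... Further [experiment_config()] overrides.
#' @return List with `report` (one row per seed x arm x module where
#'   applicable) and `runs` or `summary` detail.
#' @export
recipe <- function(name = c("error_reduction", "field_density", "gridness",
                            "entropy"),
                   seeds = NULL, n_steps = NULL, ...) {
  name <- match.arg(name)
  if (is.null(seeds)) seeds <- if (name == "entropy") 1:3 else 1:5
  if (name == "error_reduction") {
    n_steps <- if (is.null(n_steps)) 1000 else n_steps
    rows <- list()
    for (s in seeds) {
      on <- run_simulation(experiment_config(n_steps = n_steps,
                                             warmup_steps = 2000, seed = s,
                                             ...))
      # OFF arm: corrections are the only channel from place fields to the
      # estimates, so the uncorrected integrals ARE the place_input = off run
      # for the same trajectory and grid activity
      truth <- cbind(on$trajectory$x, on$trajectory$y)
      for (m in seq_along(on$estimates))
        rows[[length(rows) + 1]] <- data.frame(
          seed = s, module = m,
          mean_error_on = mean(on$module_error[, m]),
          mean_error_off = mean(sqrt(rowSums(
            (on$pure_estimates[[m]] - truth)^2))))
    }
    report <- do.call(rbind, rows)
    report$reduced <- report$mean_error_on < report$mean_error_off
    return(list(report = report))
  }
  if (name == "field_density") {
    n_steps <- if (is.null(n_steps)) 1000 else n_steps
    rows <- list()
    for (s in seeds) {
      lo <- run_simulation(experiment_config(n_steps = n_steps, seed = s,
                                             field_mode = "fixed",
                                             n_fixed_fields = 20, ...))
      hi <- run_simulation(experiment_config(n_steps = n_steps, seed = s,
                                             field_mode = "fixed",
                                             n_fixed_fields = 200, ...),
                           stack = lo$stack, traj = lo$trajectory)
      for (m in seq_along(lo$estimates))
        rows[[length(rows) + 1]] <- data.frame(
          seed = s, module = m,
          mean_error_pf20 = mean(lo$module_error[, m]),
          mean_error_pf200 = mean(hi$module_error[, m]))
    }
    report <- do.call(rbind, rows)
    report$denser_better <- report$mean_error_pf200 < report$mean_error_pf20
    return(list(report = report))
  }
  if (name == "gridness") {
    n_steps <- if (is.null(n_steps)) 10000 else n_steps
    rows <- list()
    for (s in seeds) for (st in c("center_biased", "wall_following")) {
      g <- stack_gridness(experiment_config(style = st, n_steps = n_steps,
                                            seed = s, ...))
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, style = st,
        mean_hex = mean(g$hex, na.rm = TRUE),
        mean_square = mean(g$square, na.rm = TRUE),
        n_scored = sum(is.finite(g$hex)))
    }
    return(list(report = do.call(rbind, rows)))
  }
  # entropy
  n_steps <- if (is.null(n_steps)) 10000 else n_steps
  runs <- lapply(seeds, function(s)
    run_simulation(experiment_config(n_steps = n_steps, seed = s, ...)))
  report <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    r <- runs[[i]]
    tail_w <- max(1, round(0.2 * n_steps))
    nf <- r$n_fields
    data.frame(seed = seeds[i], final_fields = nf[n_steps],
               tail_change = (max(nf[(n_steps - tail_w + 1):n_steps]) -
                                min(nf[(n_steps - tail_w + 1):n_steps])) /
                 max(1, nf[n_steps]),
               final_H = r$entropy[n_steps, "H"])
  }))
  list(report = report, runs = runs)
}

#' Gridness of every cell in the grid stack for one trajectory
#'
#' Runs the isolated grid network over the configured trajectory, builds a
#' rate map for each of the `5 x Nx x Ny` cells and scores its
#' autocorrelogram.
#'
#' @param config An [experiment_config()] (only arena/trajectory/CAN fields
#'   are used).
#' @param bin_size,smooth_sd Rate-map parameters.
#' @return Data frame `module, neuron, hex, square`.
#' @export
stack_gridness <- function(config, bin_size = 2.5, smooth_sd = 1) {
  cf <- config
  ar <- arena(side_length = cf$L, n_landmarks = cf$n_landmarks, fov = cf$fov,
              seed = derive_seed(cf$seed, "landmarks"))
  traj <- generate_trajectory(cf$style, cf$n_steps, ar,
                              seed = derive_seed(cf$seed, "trajectory"),
                              speed_max = cf$speed_max)
  stack <- module_stack(gains = cf$gains, seed = cf$seed,
                        spacing_factor = cf$spacing_factor, I_a = cf$I_a,
                        sigma_w = cf$sigma_w, T_shift = cf$T_shift,
                        tau = cf$tau, beta = cf$beta)
  gr <- stack_run(stack, traj, record_activity = TRUE)
  nb <- as.integer(round(cf$L / bin_size))
  ix <- pmin(pmax(floor(traj$x / bin_size) + 1, 1), nb)
  iy <- pmin(pmax(floor(traj$y / bin_size) + 1, 1), nb)
  idx <- ix + nb * (iy - 1)
  counts <- tabulate(idx, nb * nb)
  out <- list()
  for (m in seq_along(stack$modules)) {
    act <- gr$activity[[m]]
    sums <- rowsum(act, idx)                       # bins present x neurons
    full <- matrix(0, nb * nb, ncol(act))
    full[as.integer(rownames(sums)), ] <- sums
    hex <- sq <- rep(NA_real_, ncol(act))
    for (j in seq_len(ncol(act))) {
      r <- full[, j] / counts
      r[counts == 0] <- NA
      rm <- matrix(r, nb, nb)
      if (smooth_sd > 0) rm <- smooth_na(rm, smooth_sd)
      ac <- autocorrelogram(rm)
      hex[j] <- gridness_hex(ac)
      sq[j] <- gridness_square(ac)
    }
    out[[m]] <- data.frame(module = m, neuron = seq_len(ncol(act)),
                           hex = hex, square = sq)
  }
  do.call(rbind, out)
}
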