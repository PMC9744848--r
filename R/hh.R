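#' Hodgkin-Huxley parameters and state
#'
#' Classic squid-axon Hodgkin-Huxley single-compartment model used to decide
#' whether a place cell "fires" during a simulation step.  Voltages are in mV;
#' the depolarisation variable is `v = V_m - V_r` with resting potential
#' `V_r = -65` mV.  Conductances are in mS/cm^2, reversal potentials are
#' rest-relative (E_Na = 115, E_K = -12, E_l = 10.6), membrane capacitance
#' 1 uF/cm^2, and the forward-Euler step is `dt = 0.01`.
#'
#' @param V_r Resting potential (mV).
#' @return `hh_params()`: named list of constants. `hh_state()`: named numeric
#'   vector `(V, m, h, n)` at the standard initial values.
#' @export
hh_params <- function(V_r = -65) {
  list(V_r = V_r, g_Na = 120, g_K = 36, g_l = 0.3,
       E_Na = 115, E_K = -12, E_l = 10.6, C_m = 1, dt = 0.01)
}

#' @rdname hh_params
#' @param V,m,h,n Initial membrane potential (mV, absolute) and gating values.
#' @export
hh_state <- function(V = -65, m = 0.5, h = 0.06, n = 0.5) {
  c(V = V, m = m, h = h, n = n)
}

hh_rates <- function(v) {
  # exp((25-v)/10) = e1 exp(1.5), exp((30-v)/10) = e1 exp(2),
  # exp(-v/20) = e2^4 -- composed identically in the compiled kernel
  e1 <- exp((10 - v) / 10)
  e2 <- exp(-v / 80)
  an <- ifelse(abs(10 - v) < 1e-6, 0.1, 0.01 * (10 - v) / (e1 - 1))
  am <- ifelse(abs(25 - v) < 1e-6, 1,
               0.1 * (25 - v) / (e1 * exp(1.5) - 1))
  list(a_n = an, b_n = 0.125 * e2,
       a_m = am, b_m = 4 * exp(-v / 18),
       a_h = 0.07 * e2^4,
       b_h = 1 / (e1 * exp(2) + 1))
}

#' One forward-Euler Hodgkin-Huxley step
#'
#' Advances `(V, m, h, n)` by a single Euler step of size `dt` under external
#' current `I_ext`.  Gating variables are clamped to `[0, 1]` after the step
#' (a large `dt` can overshoot the unit interval).
#'
#' @param state Named vector from [hh_state()].
#' @param I_ext External current (model units, the repetitive-firing regime
#'   starts near I = 6; the reference drive is I = 10).
#' @param dt Step size (default 0.01).
#' @param params Constants from [hh_params()].
#' @return Updated state vector.
#' @export
hh_step <- function(state, I_ext, dt = 0.01, params = hh_params()) {
  stopifnot(dt > 0)
  v <- state[["V"]] - params$V_r
  m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  r <- hh_rates(v)
  dv <- (params$g_Na * m^3 * h * (params$E_Na - v) +
           params$g_K * n^4 * (params$E_K - v) +
           params$g_l * (params$E_l - v) + I_ext) / params$C_m
  v2 <- v + dt * dv
  if (!is.finite(v2))
    stop(sprintf("H-H integration overflow: V=%g m=%g h=%g n=%g I=%g",
                 state[["V"]], m, h, n, I_ext))
  clamp01 <- function(x) min(1, max(0, x))
  hh_state(V = v2 + params$V_r,
           m = clamp01(m + dt * (r$a_m * (1 - m) - r$b_m * m)),
           h = clamp01(h + dt * (r$a_h * (1 - h) - r$b_h * h)),
           n = clamp01(n + dt * (r$a_n * (1 - n) - r$b_n * n)))
}

#' Integrate a population of H-H units for a block of sub-steps
#'
#' Fast path used once per simulation step: each place cell's H-H unit runs
#' `n_sub` Euler sub-steps under its own constant drive. A spike is an upward
#' crossing of 0 mV.
#'
#' @param states List with numeric vectors `V`, `m`, `h`, `n` (one entry per
#'   cell).
#' @param I_ext Per-cell external current.
#' @param n_sub Number of sub-steps (default 100).
#' @param dt Sub-step size (default 0.01).
#' @param params Constants from [hh_params()].
#' @return List `V, m, h, n, spikes` (spikes = integer count per cell).
#' @export
hh_integrate <- function(states, I_ext, n_sub = 100, dt = 0.01,
                         params = hh_params()) {
  stopifnot(dt > 0, n_sub >= 1)
  hh_integrate_cpp(states$V, states$m, states$h, states$n,
                   rep_len(I_ext, length(states$V)), as.integer(n_sub), dt,
                   params$V_r, params$g_Na, params$g_K, params$g_l,
                   params$E_Na, params$E_K, params$E_l, params$C_m)
}
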