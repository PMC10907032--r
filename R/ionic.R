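# Single-cell ionic model: six membrane currents (I_Na, I_Ca,L, I_Kr, I_Ks,
# I_K1, I_to), a voltage-dependent Na+ inactivation time constant, and a
# forward-Euler state update. All gating except h and w is instantaneous.

#' Sodium inactivation time constant
#'
#' The baseline curve tau_h0(v) is a plateau floor plus an asymmetric bump
#' peaked in the phase-3/diastolic range: a narrow Gaussian flank on the
#' hyperpolarized side (fast diastolic recovery) and a flat-topped quartic
#' flank on the depolarized side that protects the wavefront foot while
#' still dropping below 1 ms for v >= -30 mV (rapid closure of I_Na at the
#' plateau); the maximum (about 7 ms under control) sits near -72 mV. An
#' optional shelf (th_up, disabled by default) can hold tau_h up during the
#' transient overshoot. The effective time constant is
#' \code{tauh_scale * (1 + ca_alpha * ca_d) * tau_h0(v)}: drugs slow recovery
#' through \code{tauh_scale}, and accumulated diastolic calcium slows it
#' further through the memory term.
#'
#' @param v membrane potential (mV), vectorized.
#' @param params a \code{model_params} object.
#' @param ca_d diastolic-calcium memory value (default 0).
#' @return time constant(s) in ms.
#' @export
tau_h <- function(v, params, ca_d = 0) {
  sg <- ifelse(v >= params[["th_mid"]], params[["th_sig"]],
               params[["th_sig_l"]])
  z <- (v - params[["th_mid"]]) / sg
  ex <- ifelse(v >= params[["th_mid"]], exp(-z^6), exp(-z^2))
  shelf <- params[["th_up"]] / (1 + exp(-(v - 2) / 4))
  t0 <- params[["th_floor"]] + params[["th_amp"]] * ex + shelf
  params[["tauh_scale"]] * (1 + params[["ca_alpha"]] * ca_d) * t0
}

#' Steady-state sodium availability curve
#'
#' \code{1 / (1 + exp((v - (eh_mid + eh_shift)) / kh))}. The drug-induced
#' availability shift acts on this curve only, not on the time constant.
#'
#' @inheritParams tau_h
#' @return availability in [0, 1], vectorized over \code{v}.
#' @export
h_inf <- function(v, params) {
  1 / (1 + exp((v - (params[["eh_mid"]] + params[["eh_shift"]])) / params[["kh"]]))
}

# steady-state I_Ca,L inactivation
w_inf <- function(v, params) {
  1 / (1 + exp((v - params[["vw"]]) / params[["kw"]]))
}

#' Instantaneous membrane currents
#'
#' Computes the six current densities at a given state. Inward currents are
#' negative. I_Na uses instantaneous cubed activation and the h gate; I_Ca,L
#' uses a Gaussian activation window (active roughly between -30 and -5 mV)
#' and the w gate; the potassium currents are instantaneously gated.
#'
#' @param state a \code{cell_state}.
#' @param params a \code{model_params}.
#' @return named numeric vector with components \code{i_na}, \code{i_cal},
#'   \code{i_kr}, \code{i_ks}, \code{i_k1}, \code{i_to} and their sum
#'   \code{i_total} (uA/cm^2).
#' @export
ionic_currents <- function(state, params) {
  .cpp_currents(as.numeric(params), state[["v"]], state[["h"]], state[["w"]])
}

#' Advance a single cell by one forward-Euler step
#'
#' Reference R implementation of the update rule used (in compiled form) by
#' all simulation drivers: \code{v' = v - dt * (i_total + i_stim) / C_m} with
#' C_m = 1 uF/cm^2, first-order gate relaxation, and gates clipped to [0, 1].
#'
#' @param state a \code{cell_state}.
#' @param params a \code{model_params}.
#' @param i_stim stimulus current density (uA/cm^2, negative = depolarizing).
#' @param dt time step (ms).
#' @return the updated \code{cell_state}.
#' @export
step_cell <- function(state, params, i_stim = 0, dt = 0.001) {
  stopifnot(dt > 0)
  cur <- ionic_currents(state, params)
  v <- state[["v"]]
  v_new <- v - dt * (cur[["i_total"]] + i_stim)
  if (!is.finite(v_new) || abs(v_new) > 200)
    stop(sprintf("numerical blow-up at t = %g ms (v)", state[["t"]]))
  th <- tau_h(v, params, state[["ca_d"]])
  h_new <- state[["h"]] + dt * (h_inf(v, params) - state[["h"]]) / th
  w_new <- state[["w"]] + dt * (w_inf(v, params) - state[["w"]]) / params[["tau_w"]]
  ica <- abs(cur[["i_cal"]])
  ca_new <- state[["ca_d"]] +
    dt * (params[["ca_gain"]] * ica - params[["ca_decay"]] * state[["ca_d"]])
  cell_state(v_new, min(max(h_new, 0), 1), min(max(w_new, 0), 1),
             max(ca_new, 0), state[["t"]] + dt)
}

#' Initial (resting) state
#'
#' Membrane potential -88 mV, gates at their steady-state values at -88 mV,
#' diastolic calcium zero — the common initial condition for all simulations.
#'
#' @param params a \code{model_params}.
#' @return a \code{cell_state}.
#' @export
initial_state <- function(params) {
  v0 <- -88
  cell_state(v0, h_inf(v0, params), w_inf(v0, params), 0, 0)
}

# Low-level cell driver around the compiled kernel.
# stim_times are onsets (ms from state$t); returns beats data frame, trace,
# final state.
cell_run <- function(params, state = initial_state(params), stim_times,
                     stim_dur = 2, stim_amp = -30, t_end, dt = 0.001,
                     record_dt = 0) {
  res <- .cpp_cell_run(as.numeric(params), as.numeric(state),
                       as.numeric(stim_times), stim_dur, stim_amp,
                       t_end, dt, record_dt)
  if (isTRUE(res$error))
    stop(sprintf("numerical blow-up at t = %g ms (variant %s)",
                 res$error_t, attr(params, "label")))
  s <- res$state
  res$state <- cell_state(s[["v"]], s[["h"]], s[["w"]], s[["ca_d"]], s[["t"]])
  res
}

#' Pace a single cell to steady state
#'
#' Applies \code{n_beats} stimuli at the given basic cycle length from the
#' standard initial state and returns the final-beat recording together with
#' the state at the final stimulus onset. Capture of the final beat is
#' checked with the single-cell criterion (peak I_Na < -100 uA/cm^2).
#'
#' @param params a \code{model_params}.
#' @param bcl basic cycle length (ms).
#' @param n_beats number of paced beats (>= 1); 8 reproduces the reference
#'   protocols.
#' @param stim_dur,stim_amp stimulus duration (ms) and amplitude (uA/cm^2).
#' @param dt integration step (ms).
#' @param record_dt if > 0, the sampled V(t) trace cadence (ms).
#' @return list with \code{beats} (per-beat measurements: APD, dV/dt_max,
#'   takeoff potential, peak currents, diastolic interval, pre-stimulus
#'   state), \code{trace}, \code{pre_state} (state at final stimulus onset),
#'   \code{state} (final), and \code{converged} (diastolic values of the last
#'   two beats within 0.1 percent).
#' @export
steady_state_pace <- function(params, bcl = 400, n_beats = 8, stim_dur = 2,
                              stim_amp = -30, dt = 0.001, record_dt = 0) {
  stopifnot(n_beats >= 1, bcl > 0)
  stim_times <- seq(0, by = bcl, length.out = n_beats)
  # allow the final beat to repolarize past its cycle (APD can approach or
  # exceed the BCL in strongly potassium-blocked variants)
  res <- cell_run(params, initial_state(params), stim_times,
                  stim_dur, stim_amp, t_end = n_beats * bcl + 300, dt = dt,
                  record_dt = record_dt)
  b <- res$beats
  n <- nrow(b)
  if (b$peak_i_na[n] >= -100)
    stop(sprintf("failure to capture: peak I_Na %.1f uA/cm^2 (variant %s)",
                 b$peak_i_na[n], attr(params, "label")))
  conv <- TRUE
  if (n >= 2) {
    hv <- b$h_pre[(n - 1):n]
    wv <- b$w_pre[(n - 1):n]
    conv <- abs(diff(hv)) < 1e-3 * max(abs(hv), 1e-12) &&
      abs(diff(wv)) < 1e-3 * max(abs(wv), 1e-12)
  }
  pre <- cell_state(b$v_pre[n], b$h_pre[n], b$w_pre[n], b$ca_pre[n],
                    b$stim_time[n])
  list(beats = b, trace = res$trace, pre_state = pre, state = res$state,
       converged = conv, bcl = bcl)
}
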