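# Monodomain tissue driver (1-D cable; the 2-D sheet builds on the same
# kernel in tissue2d.R) and cable-context PES measurements.

.node_par_names <- c("g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to",
                     "eh_shift", "tauh_scale")

# Low-level driver. Node parameters are tent-decomposed around the shared
# parameter set: par_j(node) = base_j + fx * delta_h_j + fy * delta_v_j over
# (g_na, g_cal, g_kr, g_ks, g_k1, g_to, eh_shift, tauh_scale); a uniform
# medium leaves the deltas at zero.
tissue_run <- function(params, nx, ny = 1, dx = 0.01, dt = 0.001,
                       diffusion = 0.001, state0 = NULL,
                       stim_nodes, stim_times, stim_dur = 2, stim_amp = -30,
                       t_end, rec_node = -1, rec_dt = 0,
                       frame_dt = 0, frame_t0 = 0, frame_t1 = -1,
                       stop_when_quiet = FALSE, quiet_v = -80,
                       stop_node = -1, max_cross = 40,
                       delta_h = numeric(8), delta_v = numeric(8),
                       fx = numeric(nx * ny), fy = numeric(nx * ny)) {
  base8 <- unclass(params)[.node_par_names]
  res <- .cpp_tissue_run(as.numeric(params), as.numeric(base8),
                         as.numeric(delta_h), as.numeric(delta_v),
                         as.numeric(fx), as.numeric(fy),
                         as.integer(nx),
                         as.integer(ny), dx, dt, diffusion, state0,
                         as.integer(stim_nodes), as.numeric(stim_times),
                         stim_dur, stim_amp, t_end, as.integer(rec_node),
                         rec_dt, frame_dt, frame_t0, frame_t1,
                         stop_when_quiet, quiet_v, as.integer(stop_node),
                         as.integer(max_cross))
  if (isTRUE(res$error))
    stop(sprintf("tissue instability at t = %g ms (variant %s)",
                 res$error_t, attr(params, "label")))
  res
}

first_event_after <- function(times, n, t0) {
  tt <- times[seq_len(min(n, length(times)))]
  tt <- tt[!is.na(tt) & tt >= t0]
  if (length(tt) == 0) NA_real_ else tt[1]
}

#' Conduction velocity in a quiescent cable
#'
#' Stimulates one end of a fully rested cable and computes CV from the
#' activation-time difference between two interior sites (40 and 60 percent
#' of the length, away from both boundaries).
#'
#' @param params \code{model_params}.
#' @param length cable length (cm); \code{dx}, \code{dt}, \code{diffusion}
#'   the discretization (cm, ms) and diffusion coefficient (cm^2/ms).
#' @param stim_width stimulated end segment (cm).
#' @return CV in cm/ms.
#' @export
measure_cv <- function(params, length = 5, dx = 0.01, dt = 0.001,
                       diffusion = 0.001, stim_width = 0.1) {
  nx <- round(length / dx)
  r <- tissue_run(params, nx = nx, dx = dx,
                  dt = dt, diffusion = diffusion,
                  stim_nodes = 0:(round(stim_width / dx) - 1),
                  stim_times = 0, t_end = length / 0.01 + 50,
                  stop_when_quiet = TRUE)
  i1 <- round(0.4 * nx); i2 <- round(0.6 * nx)
  t1 <- first_event_after(r$up[, i1 + 1], r$n_up[i1 + 1], 0)
  t2 <- first_event_after(r$up[, i2 + 1], r$n_up[i2 + 1], 0)
  if (is.na(t1) || is.na(t2)) stop("conduction failure: CV undefined")
  (i2 - i1) * dx / (t2 - t1)
}

# --- cable PES ------------------------------------------------------------

cable_geometry <- function(length = 5, dx = 0.01, stim_width = 0.1) {
  nx <- round(length / dx)
  list(nx = nx, dx = dx, stim_nodes = 0:(round(stim_width / dx) - 1),
       rec_node = round(nx / 2))
}

# capture in tissue: the far end activates after the premature stimulus
cable_captured <- function(run, nx, t_after = 0) {
  !is.na(first_event_after(run$up[, nx], run$n_up[nx], t_after))
}

# Upward ERP scan in tissue with incremental advance of the base state:
# coarse 4-ms trials bracket the transition, then a 1-ms upward scan inside
# the bracket, so the reported ERP is the first capturing interval at the
# protocol increment. Returns the ERP, the branch state at the ERP onset,
# and the scan log.
tissue_erp_scan <- function(params, geom, branch, start, proto,
                            dt = 0.001, diffusion = 0.001,
                            trial_t = NULL, coarse = 4) {
  nx <- geom$nx
  # cap a trial at the transit time of the slowest conducting front
  if (is.null(trial_t)) trial_t <- geom$nx * geom$dx / 0.02 + 80
  inc <- proto$erp_increment
  coarse <- max(inc, coarse)
  run_seg <- function(st, stim, t_end, quiet = FALSE) {
    tissue_run(params, nx = nx, dx = geom$dx, dt = dt,
               diffusion = diffusion, state0 = st,
               stim_nodes = geom$stim_nodes,
               stim_times = if (stim) 0 else numeric(0),
               stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
               t_end = t_end, stop_when_quiet = quiet)
  }
  trial_ok <- function(st) {
    tr <- tissue_run(params, nx = nx, dx = geom$dx, dt = dt,
                     diffusion = diffusion, state0 = st,
                     stim_nodes = geom$stim_nodes, stim_times = 0,
                     stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
                     t_end = trial_t, stop_when_quiet = TRUE,
                     stop_node = nx - 1)
    cable_captured(tr, nx)
  }
  # advance the base (undisturbed) evolution from the branch point: the first
  # segment carries the preceding beat's stimulus
  states <- list(); cis <- c()
  st <- run_seg(branch, stim = TRUE, t_end = start)$state
  ci <- start
  n_trials <- 0
  repeat {
    states[[length(states) + 1]] <- st; cis <- c(cis, ci)
    n_trials <- n_trials + 1
    if (trial_ok(st)) break
    if (ci - start > proto$max_scan)
      stop(sprintf("no tissue capture within %g ms scan (variant %s)",
                   proto$max_scan, attr(params, "label")))
    st <- run_seg(st, stim = FALSE, t_end = coarse)$state
    ci <- ci + coarse
  }
  if (length(cis) == 1 || coarse == inc) {
    erp <- ci
    st_erp <- st
  } else {
    # refine inside (previous coarse point, ci] at the protocol increment
    st <- states[[length(states) - 1]]
    lo <- cis[length(cis) - 1]
    erp <- NA_real_
    for (c2 in seq(lo + inc, ci, by = inc)) {
      st <- run_seg(st, stim = FALSE, t_end = inc)$state
      n_trials <- n_trials + 1
      if (trial_ok(st)) { erp <- c2; st_erp <- st; break }
    }
    if (is.na(erp)) { erp <- ci; st_erp <- states[[length(states)]] }
  }
  list(erp = erp, state = st_erp, n_trials = n_trials)
}

#' Run the virtual PES protocol in a 1-D cable
#'
#' As \code{\link{run_pes_cell}}, with the tissue capture criterion
#' (propagation along the entire cable) and measurements taken at the cable
#' midpoint, away from the stimulus end. The takeoff potential of a beat is
#' the minimum potential at the recording site in the 12 ms preceding its
#' local activation.
#'
#' @param params calibrated \code{model_params}.
#' @param proto a \code{\link{protocol_spec}}.
#' @param length,dx cable length and spacing (cm).
#' @param dt time step (ms); \code{diffusion} in cm^2/ms.
#' @return a \code{pes_result} with context \code{"cable"}; attribute
#'   \code{cv} holds the quiescent-cable conduction velocity and
#'   \code{di_min} the S1-S2 minimum diastolic interval at the recording
#'   site.
#' @export
run_pes_cable <- function(params, proto = protocol_spec(), length = 5,
                          dx = 0.01, dt = 0.001, diffusion = 0.001) {
  geom <- cable_geometry(length, dx)
  nx <- geom$nx; rec <- geom$rec_node

  n1 <- proto$n_s1
  train <- tissue_run(params, nx = nx, dx = dx, dt = dt,
                      diffusion = diffusion,
                      stim_nodes = geom$stim_nodes,
                      stim_times = seq(0, by = proto$bcl,
                                       length.out = n1 - 1),
                      stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
                      t_end = (n1 - 1) * proto$bcl)
  if (n1 > 1 && !cable_captured(train, nx, (n1 - 2) * proto$bcl))
    stop("S1 train failed to propagate")
  branch <- train$state

  nb <- proto$n_premature + 1L
  rows <- vector("list", nb)
  erps <- rep(NA_real_, nb)
  s1_top <- NA_real_
  for (k in seq_len(nb)) {
    full <- tissue_run(params, nx = nx, dx = dx, dt = dt,
                       diffusion = diffusion, state0 = branch,
                       stim_nodes = geom$stim_nodes, stim_times = 0,
                       stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
                       t_end = proto$max_scan + 150, rec_node = rec,
                       rec_dt = 0.05, stop_when_quiet = TRUE)
    if (!cable_captured(full, nx))
      stop("stacked beat failed to propagate at its ERP")
    act <- first_event_after(full$up[, rec + 1], full$n_up[rec + 1], 0)
    rep_t <- first_event_after(full$down[, rec + 1], full$n_down[rec + 1], act)
    tr <- full$rec_trace
    pre <- tr[, "t"] > act - 12 & tr[, "t"] < act
    top <- if (any(pre)) min(tr[pre, "v"]) else NA_real_
    if (k == 1) s1_top <- top
    rows[[k]] <- data.frame(
      beat = if (k == 1) "S1" else paste0("S", k),
      apd = rep_t - act, erp = erps[k], prr = NA_real_,
      top = top, d_top = top - s1_top,
      dvdt_max = full$beats$dvdt_max[1],
      di = NA_real_, t_act = act + branch_time(branch, k, erps),
      t_rep = rep_t + branch_time(branch, k, erps),
      peak_i_na = full$beats$peak_i_na[1],
      peak_i_cal = full$beats$peak_i_cal[1])
    if (k == nb) break
    start <- rows[[k]]$apd - proto$scan_back
    if (!is.finite(start)) stop("cannot start ERP scan: undefined APD")
    scan <- tissue_erp_scan(params, geom, branch, start = start,
                            proto = proto, dt = dt, diffusion = diffusion)
    erps[k + 1L] <- scan$erp
    branch <- scan$state
  }

  res <- do.call(rbind, rows)
  n <- nrow(res)
  res$prr[-1] <- res$erp[-1] - res$apd[-n]
  res$di[-1] <- res$t_act[-1] - res$t_rep[-n]
  res$t_act <- NULL; res$t_rep <- NULL
  di <- res$di[-1]
  cv <- tryCatch(measure_cv(params, length = length, dx = dx, dt = dt,
                            diffusion = diffusion), error = function(e) NA_real_)
  structure(res, class = c("pes_result", "data.frame"),
            context = "cable", label = attr(params, "label"),
            di_min = if (length(di)) suppressWarnings(min(di, na.rm = TRUE)) else NA_real_,
            cv = cv)
}

# absolute time offset of the k-th branch point: sum of preceding ERPs
branch_time <- function(branch, k, erps) {
  if (k <= 1) 0 else sum(erps[2:k])
}

#' Minimum S1-S2 diastolic interval in a cable
#'
#' Runs the S1 train, scans S2 coupling intervals at the protocol increment,
#' and returns the diastolic interval of the shortest fully propagating S2 at
#' the recording site: DI_min = S2 activation minus undisturbed S1
#' repolarization.
#'
#' @inheritParams run_pes_cable
#' @return list with \code{di_min} (ms), \code{erp} (shortest propagating
#'   coupling interval, ms), and the S1 measurements.
#' @export
measure_di_min_cable <- function(params, proto = protocol_spec(), length = 5,
                                 dx = 0.01, dt = 0.001, diffusion = 0.001) {
  p2 <- proto; p2$n_premature <- 1L
  pes <- run_pes_cable(params, p2, length = length, dx = dx, dt = dt,
                       diffusion = diffusion)
  list(di_min = attr(pes, "di_min"), erp = pes$erp[2],
       s1 = as.data.frame(pes)[1, ], pes = pes)
}
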