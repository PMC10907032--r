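# Virtual programmed electrical stimulation (S1 x n + S2-S4 ERP search) in
# single cells and 1-D cables, with beat-level measurements.

#' PES protocol settings
#'
#' Defaults reproduce the reference protocol: eight S1 beats at BCL 400 ms,
#' 2-ms stimuli of -30 uA/cm^2 (about twice threshold), ERP determined for
#' three premature beats using 1-ms increments (5 ms in 2-D).
#'
#' @param bcl S1 basic cycle length (ms).
#' @param n_s1 number of S1 beats.
#' @param stim_dur,stim_amp stimulus duration (ms) and amplitude (uA/cm^2,
#'   negative = depolarizing).
#' @param erp_increment ERP scan increment (ms).
#' @param n_premature number of premature beats (S2...).
#' @param scan_back scan start offset: the search begins at the preceding
#'   beat's APD minus this many ms (guaranteed sub-ERP).
#' @param max_scan abort the search beyond start + max_scan (ms).
#' @return a \code{protocol_spec} list.
#' @export
protocol_spec <- function(bcl = 400, n_s1 = 8, stim_dur = 2, stim_amp = -30,
                          erp_increment = 1, n_premature = 3, scan_back = 50,
                          max_scan = 600) {
  stopifnot(erp_increment > 0, stim_amp < 0, n_s1 >= 1, n_premature >= 1)
  structure(list(bcl = bcl, n_s1 = n_s1, stim_dur = stim_dur,
                 stim_amp = stim_amp, erp_increment = erp_increment,
                 n_premature = n_premature, scan_back = scan_back,
                 max_scan = max_scan),
            class = "protocol_spec")
}

#' Single-cell capture criterion
#'
#' A premature response is suprathreshold when its peak sodium current is
#' more negative than -100 uA/cm^2 (strict inequality; exactly -100 is not
#' captured).
#'
#' @param peak_i_na peak (most negative) I_Na after the stimulus (uA/cm^2).
#' @return logical.
#' @export
capture_test_cell <- function(peak_i_na) {
  is.finite(peak_i_na) & peak_i_na < -100
}

#' Action potential duration of a sampled trace
#'
#' Time from the upward crossing of the depolarization threshold to the
#' downward crossing of the repolarization threshold, with linear
#' interpolation between samples.
#'
#' @param trace matrix with columns \code{t} and \code{v} (or a two-column
#'   matrix time/voltage).
#' @param depol,repol thresholds (mV); the reference values are -30 and -75.
#' @return APD in ms.
#' @export
measure_apd <- function(trace, depol = -30, repol = -75) {
  t <- if ("t" %in% colnames(trace)) trace[, "t"] else trace[, 1]
  v <- if ("v" %in% colnames(trace)) trace[, "v"] else trace[, 2]
  up <- which(v[-length(v)] < depol & v[-1] >= depol)
  if (length(up) == 0) stop("undefined APD: trace never crosses ", depol, " mV")
  i <- up[1]
  t_up <- t[i] + (t[i + 1] - t[i]) * (depol - v[i]) / (v[i + 1] - v[i])
  dn <- which(v[-length(v)] >= repol & v[-1] < repol)
  dn <- dn[t[dn] >= t_up]
  if (length(dn) == 0) stop("undefined APD: no ", repol, " mV repolarization")
  j <- dn[1]
  t_dn <- t[j] + (t[j + 1] - t[j]) * (repol - v[j]) / (v[j + 1] - v[j])
  t_dn - t_up
}

#' Takeoff potential and maximal upstroke velocity of a sampled trace
#'
#' TOP is the membrane potential at stimulus onset; dV/dt_max is the maximal
#' forward-difference slope after the stimulus window (the simulation drivers
#' compute it from membrane currents at full resolution instead — see
#' \code{\link{run_pes_cell}}).
#'
#' @param trace matrix with columns \code{t}, \code{v}.
#' @param stim_onset stimulus onset time (ms).
#' @param stim_dur stimulus window excluded from the slope (ms).
#' @return \code{measure_top}: potential in mV; \code{measure_dvdt_max}:
#'   slope in mV/ms.
#' @export
measure_top <- function(trace, stim_onset) {
  t <- trace[, "t"]; v <- trace[, "v"]
  approx(t, v, xout = stim_onset, rule = 2)$y
}

#' @rdname measure_top
#' @export
measure_dvdt_max <- function(trace, stim_onset = -Inf, stim_dur = 2) {
  t <- trace[, "t"]; v <- trace[, "v"]
  dv <- diff(v) / diff(t)
  tm <- t[-length(t)]
  keep <- tm < stim_onset | tm >= stim_onset + stim_dur
  max(dv[keep])
}

# ---------------------------------------------------------------------------
# cell PES
# ---------------------------------------------------------------------------

# Upward 1-ms-increment ERP scan for a cell, branching off pre-computed
# states along the undisturbed preceding beat (exact: the premature stimulus
# cannot influence the trajectory before its own onset).
cell_erp_scan <- function(params, branch_state, start, proto,
                          capture_window = 60) {
  inc <- proto$erp_increment
  # states along the preceding beat at scan candidates
  base <- cell_run(params, branch_state, stim_times = 0,
                   t_end = start + proto$max_scan + 1,
                   stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
                   record_dt = inc)
  tr <- base$trace
  rel_t <- tr[, "t"] - branch_state[["t"]]
  cis <- seq(start, start + proto$max_scan, by = inc)
  for (ci in cis) {
    i <- which.min(abs(rel_t - ci))
    st <- cell_state(tr[i, "v"], tr[i, "h"], tr[i, "w"], tr[i, "ca_d"],
                     tr[i, "t"])
    trial <- cell_run(params, st, stim_times = 0, t_end = capture_window,
                      stim_dur = proto$stim_dur, stim_amp = proto$stim_amp)
    if (capture_test_cell(trial$beats$peak_i_na[1])) {
      return(list(erp = ci, n_trials = match(ci, cis)))
    }
  }
  stop(sprintf("no capture within %g ms scan (variant %s)",
               proto$max_scan, attr(params, "label")))
}

#' Run the virtual PES protocol in a single cell
#'
#' Delivers the S1 train, then for each premature beat (S2..) scans coupling
#' intervals upward in \code{erp_increment} steps from (preceding APD -
#' \code{scan_back}) until capture; the ERP is the shortest capturing
#' interval and the next premature beat is stacked on the response delivered
#' at its ERP. Coupling intervals are referenced to the preceding stimulus
#' onset.
#'
#' @param params calibrated \code{model_params}.
#' @param proto a \code{\link{protocol_spec}}.
#' @param dt integration step (ms).
#' @return a \code{pes_result}: data frame with one row per beat (final S1
#'   then premature beats) and columns \code{beat}, \code{apd}, \code{erp},
#'   \code{prr} (ERP_n minus APD_(n-1)), \code{top}, \code{d_top},
#'   \code{dvdt_max}, \code{di}, \code{peak_i_na}, \code{peak_i_cal};
#'   attributes \code{context}, \code{label}, \code{di_min}.
#' @export
run_pes_cell <- function(params, proto = protocol_spec(), dt = 0.001) {
  # S1 train up to the onset of the final S1
  n1 <- proto$n_s1
  train <- cell_run(params, initial_state(params),
                    stim_times = seq(0, by = proto$bcl, length.out = n1 - 1),
                    stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
                    t_end = (n1 - 1) * proto$bcl, dt = dt)
  if (n1 > 1 && !capture_test_cell(tail(train$beats$peak_i_na, 1)))
    stop("S1 train failed to capture")
  branch <- train$state

  nb <- proto$n_premature + 1L
  rows <- vector("list", nb)
  erps <- rep(NA_real_, nb)
  s1_top <- NA_real_
  for (k in seq_len(nb)) {
    # full beat from the branch state (beat = final S1 for k = 1, delivered
    # at its own ERP for k > 1)
    full <- cell_run(params, branch, stim_times = 0,
                     t_end = proto$max_scan + 100,
                     stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
                     dt = dt)
    b <- full$beats[1, ]
    if (k == 1) s1_top <- b$top
    beat_name <- if (k == 1) "S1" else paste0("S", k)
    rows[[k]] <- data.frame(
      beat = beat_name, apd = b$apd,
      erp = erps[k], prr = NA_real_,
      top = b$top, d_top = b$top - s1_top, dvdt_max = b$dvdt_max,
      di = NA_real_, t_act = b$t_act, t_rep = b$t_rep,
      peak_i_na = b$peak_i_na, peak_i_cal = b$peak_i_cal)
    if (is.na(b$apd))
      stop(sprintf("beat %s did not repolarize through -75 mV", beat_name))
    if (k == nb) break

    scan <- cell_erp_scan(params, branch, start = b$apd - proto$scan_back,
                          proto = proto)
    erps[k + 1L] <- scan$erp
    # advance the branch state to the premature stimulus onset at its ERP
    adv <- cell_run(params, branch, stim_times = 0, t_end = scan$erp,
                    stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
                    dt = dt)
    branch <- adv$state
  }

  res <- do.call(rbind, rows)
  # PRR_n = ERP_n - APD_(n-1); DI_n = activation_n - undisturbed
  # repolarization_(n-1) (negative when the premature upstroke encroaches on
  # the preceding repolarization)
  n <- nrow(res)
  res$prr[-1] <- res$erp[-1] - res$apd[-n]
  res$di[-1] <- res$t_act[-1] - res$t_rep[-n]
  res$t_act <- NULL; res$t_rep <- NULL
  di <- res$di[-1]
  structure(res, class = c("pes_result", "data.frame"),
            context = "cell", label = attr(params, "label"),
            di_min = if (length(di)) suppressWarnings(min(di, na.rm = TRUE)) else NA_real_,
            cv = NA_real_)
}

#' @export
print.pes_result <- function(x, ...) {
  cat(sprintf("<pes_result> %s (%s)\n", attr(x, "label"), attr(x, "context")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) round(col, 2))
  print(df, row.names = FALSE)
  if (is.finite(attr(x, "di_min")))
    cat(sprintf("  DI_min = %.2f ms\n", attr(x, "di_min")))
  if (is.finite(attr(x, "cv")))
    cat(sprintf("  CV = %.4f cm/ms\n", attr(x, "cv")))
  invisible(x)
}

#' Mean post-repolarization refractoriness over the premature beats
#' @param pes a \code{pes_result}.
#' @return mean of the S2.. PRR values (ms).
#' @export
mean_prr <- function(pes) mean(pes$prr[-1], na.rm = TRUE)
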