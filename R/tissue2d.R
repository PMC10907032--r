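# 2-D isotropic monodomain sheets with pyramidic parameter gradients,
# corner-stimulus PES, and APD-gradient measurement.

#' Build a gradient sheet
#'
#' Per-node parameters interpolate between a corner (control) and a center
#' (HF or HF + drug) parameterization along tent ("triangular") blends:
#' g_Ca,L along the vertical axis, the potassium conductances along the
#' horizontal axis, so the largest APD occurs near the center and the
#' bottom-left and top-right corners carry exactly the corner model. The
#' sodium conductance and the drug kinetics fields (tauh_scale, eh_shift)
#' blend along the horizontal tent together with the potassium conductances,
#' so the corners are truly drug-free.
#'
#' @param corner_params,center_params \code{model_params}; they must share
#'   all shape constants (only conductances, eh_shift and tauh_scale may
#'   differ).
#' @param length sheet edge (cm); \code{dx} node spacing (cm).
#' @param diffusion diffusion coefficient (cm^2/ms).
#' @return a \code{tissue_field}: node-parameter matrix plus geometry.
#' @export
build_gradient_sheet <- function(corner_params, center_params, length = 20,
                                 dx = 0.02, diffusion = 0.001) {
  shapes <- setdiff(.param_names, .node_par_names)
  if (!isTRUE(all.equal(unclass(corner_params)[shapes],
                        unclass(center_params)[shapes])))
    stop("corner and center parameterizations differ in shape constants")
  n <- round(length / dx)
  if (abs(n * dx - length) > 1e-9) stop("length must be a multiple of dx")
  xs <- (seq_len(n) - 1) / (n - 1)      # node coordinates in [0, 1]
  f_k <- 1 - abs(2 * xs - 1)            # horizontal tent (0 at both edges)
  f_cal <- 1 - abs(2 * xs - 1)          # vertical tent

  co <- unclass(corner_params)[.node_par_names]
  ce <- unclass(center_params)[.node_par_names]
  fx <- rep(f_k, times = n)             # node i = iy * n + ix (row-major y)
  fy <- rep(f_cal, each = n)
  horiz <- c("g_na", "g_kr", "g_ks", "g_k1", "g_to", "eh_shift", "tauh_scale")
  delta_h <- setNames(numeric(8), .node_par_names)
  delta_h[horiz] <- ce[horiz] - co[horiz]
  delta_v <- setNames(numeric(8), .node_par_names)
  delta_v["g_cal"] <- ce[["g_cal"]] - co[["g_cal"]]

  fld <- structure(list(delta_h = delta_h, delta_v = delta_v,
                        fx = fx, fy = fy, nx = n, ny = n, dx = dx,
                        diffusion = diffusion, length = length,
                        corner = corner_params, center = center_params),
                   class = "tissue_field")
  if (any(field_pnode(fld)[1:6, ] < 0))
    stop("negative conductance in gradient field")
  fld
}

#' Per-node parameter matrix of a gradient field
#'
#' Materializes the tent-decomposed node parameters as an 8 x (nx*ny)
#' matrix (rows: g_na, g_cal, g_kr, g_ks, g_k1, g_to, eh_shift, tauh_scale),
#' mainly for inspection and testing; the solvers use the decomposition
#' directly.
#'
#' @param field a \code{tissue_field}.
#' @return numeric matrix.
#' @export
field_pnode <- function(field) {
  co <- unclass(field$corner)[.node_par_names]
  m <- matrix(co, nrow = 8, ncol = field$nx * field$ny,
              dimnames = list(.node_par_names, NULL))
  m + outer(field$delta_h, field$fx) + outer(field$delta_v, field$fy)
}

#' @export
print.tissue_field <- function(x, ...) {
  cat(sprintf("<tissue_field> %g x %g cm (%d x %d nodes, dx %g cm)\n",
              x$length, x$length, x$nx, x$ny, x$dx))
  cat(sprintf("  corner: %s   center: %s\n", attr(x$corner, "label"),
              attr(x$center, "label")))
  invisible(x)
}

sheet_stim_nodes <- function(field, size_cm = 0.1) {
  w <- max(1, round(size_cm / field$dx))
  ix <- rep(0:(w - 1), times = w)
  iy <- rep(0:(w - 1), each = w)
  iy * field$nx + ix
}

sheet_run_seg <- function(field, state0, stim, proto, t_end, dt,
                          max_cross = 6, quiet = FALSE, frame_dt = 0,
                          frame_t0 = 0, frame_t1 = -1, stop_node = -1) {
  tissue_run(field$corner, nx = field$nx, ny = field$ny,
             dx = field$dx, dt = dt, diffusion = field$diffusion,
             state0 = state0, stim_nodes = sheet_stim_nodes(field),
             stim_times = if (stim) 0 else numeric(0),
             stim_dur = proto$stim_dur, stim_amp = proto$stim_amp,
             t_end = t_end, stop_when_quiet = quiet,
             max_cross = max_cross, frame_dt = frame_dt,
             frame_t0 = frame_t0, frame_t1 = frame_t1,
             stop_node = stop_node,
             delta_h = field$delta_h, delta_v = field$delta_v,
             fx = field$fx, fy = field$fy)
}

# capture in 2-D: the far (upper-right) corner region activates in the trial
sheet_captured <- function(run, field) {
  far <- field$ny * field$nx - 1
  !is.na(first_event_after(run$up[, far + 1], run$n_up[far + 1], 0))
}

#' Run the virtual PES protocol in a 2-D gradient sheet
#'
#' S1 pacing from the bottom-left corner (0.1 x 0.1 cm footprint), then the
#' ERP of each premature beat is determined at the same site with the 2-D
#' increment (5 ms); each premature beat is delivered at its ERP, and after
#' the last one the simulation continues for \code{horizon} ms with voltage
#' frames recorded for classification.
#'
#' @param field a \code{tissue_field} from \code{\link{build_gradient_sheet}}.
#' @param proto a \code{\link{protocol_spec}} (use \code{erp_increment = 5}).
#' @param dt time step (ms; the reference 2-D value is 0.01).
#' @param horizon continuation after the last premature beat (ms; 2000 at
#'   full scale).
#' @param frame_dt cadence of recorded voltage frames (ms).
#' @return a \code{sheet_run}: per-beat ERPs, final-S1 APD map, activation
#'   data and frames of the post-stimulus window.
#' @export
run_pes_2d <- function(field, proto = protocol_spec(erp_increment = 5),
                       dt = 0.01, horizon = 2000, frame_dt = 2) {
  n1 <- proto$n_s1
  # upper bound on diagonal transit (slow-CV allowance); quiet-stop ends
  # segments early when activity dies sooner
  travel <- 50 * field$length + 100
  train <- sheet_run_seg(field, NULL, stim = FALSE, proto, t_end = 0.02,
                         dt = dt)  # rest init only
  state <- train$state
  if (n1 > 1) {
    for (k in seq_len(n1 - 1)) {
      seg <- sheet_run_seg(field, state, stim = TRUE, proto,
                           t_end = proto$bcl, dt = dt)
      if (k == 1 && !sheet_captured(seg, field))
        stop("S1 failed to propagate across the sheet")
      state <- seg$state
    }
  }
  branch <- state   # at onset of the final S1

  erps <- rep(NA_real_, proto$n_premature + 1L)
  apd_map <- NULL
  act_maps <- list()
  prev_apd <- NA_real_
  final <- NULL
  for (k in seq_len(proto$n_premature + 1L)) {
    last <- k == proto$n_premature + 1L
    t_end <- if (last) horizon else max(travel + 100, 700)
    full <- sheet_run_seg(field, branch, stim = TRUE, proto, t_end = t_end,
                          dt = dt, max_cross = if (last) 30 else 6,
                          quiet = TRUE,
                          frame_dt = if (last) frame_dt else 0,
                          frame_t0 = 0, frame_t1 = if (last) t_end else -1)
    N <- field$nx * field$ny
    act <- vapply(seq_len(N), function(i)
      first_event_after(full$up[, i], full$n_up[i], 0), numeric(1))
    act_maps[[k]] <- matrix(act, field$nx, field$ny)
    if (k == 1) {
      rep_t <- vapply(seq_len(N), function(i)
        first_event_after(full$down[, i], full$n_down[i], 0), numeric(1))
      apd_map <- matrix(rep_t - act, field$nx, field$ny)
      site <- sheet_stim_nodes(field)[1] + 1
      prev_apd <- apd_map[site]
    }
    if (last) { final <- full; break }
    scan <- sheet_erp_search(field, branch, start = prev_apd - proto$scan_back,
                             proto = proto, dt = dt, travel = travel)
    erps[k + 1L] <- scan$erp
    branch <- scan$state
    prev_apd <- if (!is.na(scan$apd)) scan$apd else prev_apd
  }

  structure(list(field = field, proto = proto, erps = erps,
                 apd_map = apd_map, act_maps = act_maps,
                 final = final, horizon = horizon, dt = dt,
                 frame_dt = frame_dt,
                 label = attr(field$center, "label")),
            class = "sheet_run")
}

# upward ERP scan at the 2-D increment with incremental base advance
sheet_erp_search <- function(field, branch, start, proto, dt, travel) {
  inc <- proto$erp_increment
  st <- sheet_run_seg(field, branch, stim = TRUE, proto, t_end = start,
                      dt = dt)$state
  ci <- start
  repeat {
    trial <- sheet_run_seg(field, st, stim = TRUE, proto, t_end = travel,
                           dt = dt, quiet = TRUE,
                           stop_node = field$ny * field$nx - 1)
    if (sheet_captured(trial, field)) break
    if (ci - start > proto$max_scan)
      stop("no 2-D capture within the ERP scan")
    st <- sheet_run_seg(field, st, stim = FALSE, proto, t_end = inc,
                        dt = dt)$state
    ci <- ci + inc
  }
  # APD of the premature beat at the stimulus site, for the next scan start
  site <- sheet_stim_nodes(field)[1] + 1
  a <- first_event_after(trial$up[, site], trial$n_up[site], 0)
  r <- first_event_after(trial$down[, site], trial$n_down[site], a)
  list(erp = ci, state = st, apd = if (is.na(a) || is.na(r)) NA_real_ else r - a)
}

#' @export
print.sheet_run <- function(x, ...) {
  cat(sprintf("<sheet_run> center %s, %g cm sheet\n", x$label,
              x$field$length))
  cat("  premature-beat ERPs (ms):",
      paste(x$erps[-1], collapse = ", "), "\n")
  cat(sprintf("  APD gradient: %.2f ms/cm\n", measure_apd_gradient(x)))
  invisible(x)
}

#' APD gradient of a sheet run
#'
#' (APD_max - APD at the lower-left corner) divided by the euclidean
#' distance between the two sites, from the final S1 APD map (units ms/cm).
#'
#' @param run a \code{sheet_run}.
#' @return gradient in ms/cm.
#' @export
measure_apd_gradient <- function(run) {
  m <- run$apd_map
  dx <- run$field$dx
  i <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  corner <- m[1, 1]
  d <- sqrt(sum(((i - c(1, 1)) * dx)^2))
  if (d == 0) return(0)
  (m[i[1], i[2]] - corner) / d
}
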