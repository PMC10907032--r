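# Reentry-outcome classification for 2-D PES runs: activation bookkeeping,
# phase-singularity detection, wave-break and reentry labels.

#' Per-node activation events of a sheet run
#'
#' Upward -30 mV crossings per node during the post-stimulus window of the
#' final premature beat (crossings are deduplicated by the action potential
#' itself: a node cannot re-cross upward before repolarizing).
#'
#' @param run a \code{sheet_run}.
#' @return list of numeric vectors, one per node (activation times, ms).
#' @export
detect_activations <- function(run) {
  f <- run$final
  N <- run$field$nx * run$field$ny
  lapply(seq_len(N), function(i) {
    k <- min(f$n_up[i], nrow(f$up))
    if (k == 0) numeric(0) else f$up[seq_len(k), i]
  })
}

# time of the last stimulated activation sweep: the final premature beat's
# own wave has passed every node it will reach by its activation-map times
stimulated_sweep_end <- function(run) {
  a <- run$act_maps[[length(run$act_maps)]]
  if (all(is.na(a))) 0 else max(a, na.rm = TRUE)
}

#' Count extra beats of a sheet run
#'
#' Whole-tissue activations after the final stimulated beat that
#' self-terminate: re-excitations of the stimulus site after its own
#' stimulated response, counted when the run does not remain active to the
#' horizon.
#'
#' @param run a \code{sheet_run}.
#' @return integer count.
#' @export
count_extra_beats <- function(run) {
  acts <- detect_activations(run)
  site <- sheet_stim_nodes(run$field)[1] + 1
  own <- acts[[site]]
  if (length(own) == 0) return(0L)
  # re-excitations: site activations more than 20 ms after its stimulated one
  sum(own > own[1] + 20)
}

#' Is activity sustained to the simulation horizon?
#'
#' TRUE when the tissue never became quiescent before the recorded horizon
#' (the driver stops early when every node falls below -60 mV).
#'
#' @param run a \code{sheet_run}.
#' @return logical.
#' @export
sustained_to_horizon <- function(run) {
  f <- run$final
  is.na(f$t_stop) || f$t_stop >= run$horizon - 2 * run$frame_dt
}

#' Phase maps of recorded voltage frames
#'
#' Time-delay embedding phase: \code{atan2(V(t - tau) - V*, V(t) - V*)} per
#' node, with origin \code{V* = -40} mV and delay \code{tau} (ms).
#'
#' @param run a \code{sheet_run} with recorded frames.
#' @param v_star phase-space origin (mV).
#' @param tau embedding delay (ms).
#' @return list with \code{phase} (frames x nodes matrix) and \code{times}.
#' @export
phase_map <- function(run, v_star = -40, tau = 8) {
  fr <- run$final$frames
  tt <- run$final$frame_times
  if (is.null(fr) || nrow(fr) < 3) stop("no frames recorded")
  k <- max(1L, round(tau / diff(tt[1:2])))
  idx <- (k + 1):nrow(fr)
  ph <- atan2(fr[idx - k, , drop = FALSE] - v_star,
              fr[idx, , drop = FALSE] - v_star)
  list(phase = ph, times = tt[idx])
}

# winding number of a phase field on each grid plaquette; returns indices
# (lower-left node, 0-based ix, iy) of plaquettes with winding +-1
singularities_in_frame <- function(phi, nx, ny) {
  m <- matrix(phi, nx, ny)
  d1 <- wrap_pi(m[-1, -ny, drop = FALSE] - m[-nx, -ny, drop = FALSE])
  d2 <- wrap_pi(m[-1, -1, drop = FALSE] - m[-1, -ny, drop = FALSE])
  d3 <- wrap_pi(m[-nx, -1, drop = FALSE] - m[-1, -1, drop = FALSE])
  d4 <- wrap_pi(m[-nx, -ny, drop = FALSE] - m[-nx, -1, drop = FALSE])
  wnd <- (d1 + d2 + d3 + d4) / (2 * pi)
  which(abs(wnd) > 0.5, arr.ind = TRUE)
}

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

# a singularity sitting on a node corner can wind several adjacent
# plaquettes; merge touching plaquettes into one reported singularity
cluster_plaquettes <- function(s, gap = 1.5) {
  n <- nrow(s)
  if (n <= 1) return(s)
  grp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(s[i, 1] - s[j, 1]) <= gap && abs(s[i, 2] - s[j, 2]) <= gap)
      grp[grp == grp[j]] <- grp[i]
  }
  out <- t(vapply(unique(grp), function(g)
    colMeans(s[grp == g, , drop = FALSE]), numeric(2)))
  out
}

#' Phase singularities over time
#'
#' @param run a \code{sheet_run}.
#' @param ... passed to \code{\link{phase_map}}.
#' @return data frame with one row per (frame, singularity): time, ix, iy.
#' @export
find_phase_singularities <- function(run, ...) {
  pm <- phase_map(run, ...)
  nx <- run$field$nx; ny <- run$field$ny
  out <- lapply(seq_along(pm$times), function(i) {
    s <- singularities_in_frame(pm$phase[i, ], nx, ny)
    if (nrow(s) == 0) return(NULL)
    s <- cluster_plaquettes(s)
    data.frame(t = pm$times[i], ix = s[, 1], iy = s[, 2])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(t = numeric(0), ix = integer(0),
                               iy = integer(0)) else out
}

#' Wave-break detection
#'
#' A propagating front fragments when transient phase singularities appear
#' inside the tissue (front endpoints in the interior), assessed over the
#' post-stimulus window of the final premature beat.
#'
#' @param run a \code{sheet_run}.
#' @param min_frames singularities must appear in at least this many frames.
#' @return logical.
#' @export
detect_wavebreak <- function(run, min_frames = 3) {
  s <- find_phase_singularities(run)
  if (nrow(s) == 0) return(FALSE)
  length(unique(s$t)) >= min_frames
}

#' Completed rotations around the singularity trajectory
#'
#' Total unwrapped phase advance at a probe node a few nodes away from the
#' mean singularity location, divided by 2 pi and floored: a rigidly
#' rotating pattern of period T observed for time span S yields
#' floor(S / T) full rotations.
#'
#' @param run a \code{sheet_run}.
#' @param sing optional precomputed singularity table.
#' @return integer rotation count (0 when no singularity exists).
#' @export
count_rotations <- function(run, sing = NULL) {
  if (is.null(sing)) sing <- find_phase_singularities(run)
  if (nrow(sing) == 0) return(0L)
  pm <- phase_map(run)
  nx <- run$field$nx; ny <- run$field$ny
  cx <- round(mean(sing$ix)); cy <- round(mean(sing$iy))
  px <- min(nx, cx + 4); py <- min(ny, cy)   # probe off the core
  node <- (py - 1L) * nx + px
  # only phase advance after the stimulated sweep counts: the final
  # premature beat's own activation-repolarization cycle must not be
  # mistaken for a rotation (prescribed rotating fields have no
  # activation map and use the whole record)
  sweep <- stimulated_sweep_end(run)
  keep <- if (is.finite(sweep) && sweep > 0)
    pm$times > sweep + 30 else rep(TRUE, length(pm$times))
  if (sum(keep) < 3) return(0L)
  phi <- pm$phase[keep, node]
  adv <- sum(abs(wrap_pi(diff(phi))))
  # net winding, robust to jitter: use the dominant direction
  net <- abs(sum(wrap_pi(diff(phi))))
  as.integer(floor(max(net, adv / 2) / (2 * pi)))
}

#' Classify a 2-D PES run
#'
#' Outcome vocabulary: \code{none} (no post-stimulus activity), \code{eb(n)}
#' (n self-terminating extra beats), \code{vt} (sustained single-rotor
#' reentry), \code{vfvt} (sustained single-rotor reentry with cycle length
#' below \code{fast_cl} ms), \code{nsvf} (multi-rotor activity that
#' self-terminates), \code{vf} (sustained multi-rotor activity). The VT/VF
#' split uses the mean concurrent singularity count over the sustained
#' window (threshold \code{vf_threshold}).
#'
#' @param run a \code{sheet_run}.
#' @param vf_threshold mean concurrent singularities above which sustained
#'   activity is fibrillation.
#' @param fast_cl cycle length (ms) below which sustained VT is "very fast".
#' @return a \code{reentry_outcome}: list with \code{label},
#'   \code{wave_break}, \code{sustained_2s}, \code{n_rotations},
#'   \code{extra_beats}, \code{mean_singularities}, \code{cycle_length}.
#' @export
classify_run <- function(run, vf_threshold = 1.5, fast_cl = 150) {
  sing <- find_phase_singularities(run)
  wb <- nrow(sing) > 0 && length(unique(sing$t)) >= 3
  rot <- count_rotations(run, sing)
  eb <- count_extra_beats(run)
  sus <- sustained_to_horizon(run)

  # cycle length & concurrency over the tail of the run
  cl <- NA_real_
  mean_sing <- 0
  if (nrow(sing) > 0) {
    conc <- table(sing$t)
    mean_sing <- mean(conc)
    site_acts <- detect_activations(run)[[which.max(
      tabulate((sing$iy - 1L) * run$field$nx + sing$ix + 1L,
               run$field$nx * run$field$ny))]]
    post <- site_acts[site_acts > stimulated_sweep_end(run)]
    if (length(post) >= 2) cl <- mean(diff(post))
  }

  label <-
    if (rot < 1 && eb == 0) "none"
    else if (!sus) {
      if (mean_sing > vf_threshold) "nsvf" else sprintf("eb(%d)", max(eb, rot))
    } else {
      if (mean_sing > vf_threshold) "vf"
      else if (!is.na(cl) && cl < fast_cl) "vfvt"
      else "vt"
    }

  structure(list(label = label, wave_break = wb, sustained_2s = sus,
                 n_rotations = rot, extra_beats = eb,
                 mean_singularities = mean_sing, cycle_length = cl,
                 variant = run$label),
            class = "reentry_outcome")
}

#' @export
print.reentry_outcome <- function(x, ...) {
  cat(sprintf(
    "<reentry_outcome> %s: %s (wave break: %s, sustained: %s, rotations: %d)\n",
    x$variant, x$label, x$wave_break, x$sustained_2s, x$n_rotations))
  invisible(x)
}
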