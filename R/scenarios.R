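# Configuration, scenario runner, fixtures and standard outputs.

#' Read a scenario configuration
#'
#' Flat YAML key trees; see \code{\link{run_scenario}} for the recognized
#' keys. Unknown keys raise an error naming the offending key.
#'
#' @param path YAML file path.
#' @return validated \code{scenario_config} list.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_scenario_config(cfg)
}

#' @rdname read_scenario_config
#' @param cfg a configuration list.
#' @export
validate_scenario_config <- function(cfg) {
  known <- c("scenario", "variants", "bcl", "n_s1", "n_premature",
             "erp_increment", "length", "dx", "dt", "diffusion", "horizon",
             "out_dir", "frame_dt", "calibrate", "snapshot_times")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  scen <- cfg$scenario %||% "pes_cell"
  ok <- c("calibrate", "pes_cell", "pes_cable", "table1", "table2", "reduced")
  if (!scen %in% ok)
    stop("scenario must be one of: ", paste(ok, collapse = ", "))
  if (!is.null(cfg$dt) && (cfg$dt <= 0 || cfg$dt > 0.05))
    stop("dt outside stability bounds (key: dt)")
  if (!is.null(cfg$dx) && (cfg$dx < 0.005 || cfg$dx > 0.1))
    stop("dx outside supported range (key: dx)")
  structure(cfg, class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a named scenario
#'
#' \code{"calibrate"} calibrates the requested variants and writes the
#' calibration log; \code{"pes_cell"} / \code{"pes_cable"} run the PES
#' protocol and write tidy per-beat CSVs; \code{"table1"} runs the 2-D PES
#' and classification for HF and the HF+AM variants across sheet sizes;
#' \code{"table2"} for HF, HF+DS and the HF+AM' variants at one size;
#' \code{"reduced"} runs the same 2-D pipeline at fixture scale. Every run
#' writes a provenance block (configuration and package version). The
#' pipeline contains no random number generator; identical configurations
#' produce identical summaries.
#'
#' @param cfg a \code{scenario_config} (or path to one).
#' @param quiet suppress progress messages.
#' @return list of result objects, invisibly; files under \code{out_dir}.
#' @export
run_scenario <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_scenario_config(cfg)
  cfg <- validate_scenario_config(cfg)
  out <- cfg$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  ctl <- make_control()
  variants <- cfg$variants %||% "control"
  scen <- cfg$scenario %||% "pes_cell"

  proto <- protocol_spec(bcl = cfg$bcl %||% 400, n_s1 = cfg$n_s1 %||% 8,
                         n_premature = cfg$n_premature %||% 3,
                         erp_increment = cfg$erp_increment %||% 1)

  results <- list()
  if (scen == "calibrate") {
    for (lab in variants) {
      say("calibrating ", lab)
      p <- make_variant(lab, control = ctl, calibrate = TRUE)
      results[[lab]] <- attr(p, "calibration")
    }
    log_df <- do.call(rbind, lapply(names(results), function(lab) {
      r <- results[[lab]]
      data.frame(variant = lab,
                 key = names(unlist(r)), value = unlist(r),
                 row.names = NULL)
    }))
    write.csv(log_df, file.path(out, "calibration_log.csv"),
              row.names = FALSE)
  } else if (scen %in% c("pes_cell", "pes_cable")) {
    for (lab in variants) {
      say("PES (", scen, "): ", lab)
      p <- make_variant(lab, control = ctl)
      results[[lab]] <- if (scen == "pes_cell") run_pes_cell(p, proto)
        else run_pes_cable(p, proto, length = cfg$length %||% 5,
                           dx = cfg$dx %||% 0.01, dt = cfg$dt %||% 0.001)
    }
    write.csv(pes_tidy(results), file.path(out, paste0(scen, ".csv")),
              row.names = FALSE)
  } else {
    sizes <- cfg$length %||% (if (scen == "table1") c(16, 20, 24)
                              else if (scen == "table2") 20 else 4)
    labs <- if (scen == "table1") c("hf", paste0("hf+am", 1:8))
      else if (scen == "table2") c("hf", "hf+ds", paste0("hf+am", 1:8, "p"))
      else variants
    proto$erp_increment <- cfg$erp_increment %||% 5
    rows <- list()
    for (L in sizes) for (lab in labs) {
      say("2-D PES: ", lab, " at ", L, " cm")
      center <- make_variant(lab, control = ctl)
      field <- build_gradient_sheet(ctl, center, length = L,
                                    dx = cfg$dx %||% 0.02)
      run <- run_pes_2d(field, proto, dt = cfg$dt %||% 0.01,
                        horizon = cfg$horizon %||% 2000,
                        frame_dt = cfg$frame_dt %||% 2)
      oc <- classify_run(run)
      rows[[paste(lab, L)]] <- data.frame(
        variant = lab, size_cm = L,
        gradient_ms_cm = measure_apd_gradient(run),
        erp_s2 = run$erps[2], erp_s3 = run$erps[3], erp_s4 = run$erps[4],
        outcome = oc$label, wave_break = oc$wave_break,
        sustained = oc$sustained_2s)
      results[[paste(lab, L)]] <- list(run = run, outcome = oc)
    }
    write.csv(do.call(rbind, rows),
              file.path(out, paste0(scen, "_summary.csv")),
              row.names = FALSE)
  }
  writeLines(c(paste("package:", as.character(utils::packageVersion("cardpes"))),
               paste("scenario:", scen),
               yaml::as.yaml(unclass(cfg))),
             file.path(out, "provenance.txt"))
  invisible(results)
}

#' Tidy per-beat table from PES results
#'
#' @param results named list of \code{pes_result} objects.
#' @return long data frame (variant, context, beat, metric, value).
#' @export
pes_tidy <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    df <- as.data.frame(r)
    long <- do.call(rbind, lapply(
      setdiff(names(df), "beat"),
      function(m) data.frame(variant = attr(r, "label"),
                             context = attr(r, "context"),
                             beat = df$beat, metric = m, value = df[[m]])))
    long
  }))
}

#' Reduced-scale fixtures
#'
#' Emits a fast configuration plus the property assertions the test suite
#' checks. Kinds: \code{uniform_sheet} (homogeneous control sheet: no
#' substrate, zero extra beats), \code{gradient_sheet_small} (reduced
#' gradient sheet), \code{spiral_synthetic} (prescribed rotating phase
#' pattern with known singularity count), \code{cable_short} (2.5-cm cable).
#'
#' @param kind fixture name.
#' @return list with \code{config} and \code{expect} (property manifest).
#' @export
make_fixture <- function(kind = c("uniform_sheet", "gradient_sheet_small",
                                  "spiral_synthetic", "cable_short")) {
  kind <- match.arg(kind)
  switch(kind,
    uniform_sheet = list(
      config = list(scenario = "reduced", variants = "control", length = 2.5,
                    dx = 0.02, dt = 0.02, n_s1 = 2, n_premature = 1,
                    horizon = 300, erp_increment = 5),
      expect = list(extra_beats = 0, wave_break = FALSE)),
    gradient_sheet_small = list(
      config = list(scenario = "reduced", length = 2.5, dx = 0.01, dt = 0.02,
                    n_s1 = 4, n_premature = 3, horizon = 800,
                    erp_increment = 5),
      expect = list(hf_inducible = TRUE, hf_am_inducible = FALSE)),
    spiral_synthetic = list(
      config = list(nx = 40, ny = 40, n_frames = 40, period = 120,
                    frame_dt = 4),
      expect = list(n_singularities = 1, rotations = 1)),
    cable_short = list(
      config = list(scenario = "pes_cable", length = 2.5, dx = 0.01,
                    dt = 0.001, n_s1 = 2, n_premature = 1),
      expect = list(cv_positive = TRUE)))
}

#' Synthetic rigidly rotating phase field
#'
#' Ground-truth fixture for the classifier: voltage frames
#' \code{v = -40 + 45 cos(azimuth - omega t)} around a prescribed core, which
#' carries exactly one phase singularity and completes
#' \code{n_frames * frame_dt / period} rotations.
#'
#' @param nx,ny grid size; \code{n_frames} frames at \code{frame_dt} ms;
#'   \code{period} rotation period (ms); \code{core} singularity location in
#'   node units (defaults to the grid center).
#' @return a minimal \code{sheet_run}-compatible object for the classifier.
#' @export
synthetic_spiral_run <- function(nx = 40, ny = 40, n_frames = 40,
                                 frame_dt = 4, period = 120, core = NULL) {
  if (is.null(core)) core <- c((nx + 1) / 2, (ny + 1) / 2)
  ix <- rep(seq_len(nx), times = ny) - core[1]
  iy <- rep(seq_len(ny), each = nx) - core[2]
  az <- atan2(iy, ix)
  tt <- seq(0, by = frame_dt, length.out = n_frames)
  fr <- t(vapply(tt, function(t)
    -40 + 45 * cos(az - 2 * pi * t / period), numeric(nx * ny)))
  up <- matrix(NA_real_, 2, nx * ny)
  field <- list(nx = nx, ny = ny, dx = 0.04, length = nx * 0.04,
                corner = default_control_params(),
                center = default_control_params())
  structure(list(field = field,
                 final = list(frames = fr, frame_times = tt,
                              up = up, n_up = rep(0L, nx * ny),
                              down = up, n_down = rep(0L, nx * ny),
                              t_stop = NA_real_),
                 act_maps = list(matrix(NA_real_, nx, ny)),
                 horizon = max(tt), frame_dt = frame_dt, dt = frame_dt,
                 erps = NA_real_, apd_map = matrix(NA_real_, nx, ny),
                 label = "synthetic-spiral"),
            class = "sheet_run")
}
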