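#' Run the full gait-analysis pipeline from a config file
#'
#' The config (JSON, or YAML when the `yaml` package is installed) names
#' the inputs and parameters:
#'
#' ```
#' {
#'   "inputs": {
#'     "views_2d": ["cam1.csv", "cam2.csv", "cam3.csv"],  # detections, or
#'     "series_3d": "markers.csv",                        # analysis-only path
#'     "calibration": "calibration.json",
#'     "skeleton": "h36m21"
#'   },
#'   "triangulation": {"min_confidence": 0.1, "min_views": 2, "refine": true},
#'   "filters": {"event_cutoff_hz": 3, "kinematics_cutoff_hz": 12},
#'   "compare_with": "second_system.csv",   # optional
#'   "alpha": 0.05,
#'   "seed": 1,
#'   "output_dir": "out"
#' }
#' ```
#'
#' With 2D views the keypoints are triangulated first; with `series_3d`
#' the triangulation stage is skipped. Outputs written to `output_dir`:
#' the 3D trajectory CSV, events CSV, per-cycle parameter CSV + summary,
#' angle-curve CSV (long layout), a TRC export, a run log with all
#' effective parameters, and a comparison report when `compare_with` is
#' given (cycles paired by index across the two systems).
#'
#' @param config_path path to the config file, or an equivalent named
#'   list.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config_path) {
  cfg <- if (is.list(config_path)) config_path else read_config(config_path)
  err_config <- function(...) stop(structure(
    class = c("gait_config_error", "error", "condition"),
    list(message = paste0(...), call = NULL)))
  inputs <- cfg$inputs
  if (is.null(inputs)) err_config("config has no 'inputs' section")
  outdir <- cfg$output_dir
  if (is.null(outdir)) err_config("config has no 'output_dir'")
  has2d <- !is.null(inputs$views_2d) && length(inputs$views_2d) > 0
  has3d <- !is.null(inputs$series_3d)
  if (!has2d && !has3d) {
    err_config("config needs inputs$views_2d (+calibration) or inputs$series_3d")
  }
  if (has2d && is.null(inputs$calibration)) {
    err_config("2D views given but no inputs$calibration")
  }
  for (p in c(unlist(inputs$views_2d), inputs$calibration, inputs$series_3d,
              cfg$compare_with)) {
    if (!file.exists(p)) err_config("input file not found: ", p)
  }
  skeleton <- as_skeleton(inputs$skeleton %||% "h36m21")
  filters <- cfg$filters %||% list()
  event_hz <- filters$event_cutoff_hz %||% 3
  kin_hz <- filters$kinematics_cutoff_hz %||% 12
  alpha <- cfg$alpha %||% 0.05
  seed <- cfg$seed %||% 1L

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run_log.txt")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  logmsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S "), ...), logcon)
  }
  logmsg("gaitless ", as.character(utils::packageVersion("gaitless")),
         " | R ", R.version.string)
  logmsg("seed=", seed, " alpha=", alpha, " event_cutoff_hz=", event_hz,
         " kinematics_cutoff_hz=", kin_hz, " skeleton=", skeleton$name)

  if (has2d) {
    logmsg("triangulating ", length(inputs$views_2d), " views")
    cams <- read_calibration(inputs$calibration)
    views <- lapply(unlist(inputs$views_2d), read_keypoints_2d,
                    skeleton = skeleton)
    tri <- cfg$triangulation %||% list()
    series <- triangulate_series(
      views, cams,
      min_confidence = tri$min_confidence %||% 0.1,
      min_views = tri$min_views %||% 2L,
      refine = tri$refine %||% TRUE)
  } else {
    logmsg("reading 3D series (triangulation skipped)")
    series <- read_keypoints_3d(inputs$series_3d, skeleton = skeleton)
  }
  write_keypoints_3d(series, file.path(outdir, "trajectories_3d.csv"))

  artifacts <- analyze_series(series, outdir, event_hz, kin_hz, logmsg)

  if (!is.null(cfg$compare_with)) {
    logmsg("comparing against ", cfg$compare_with)
    other <- read_keypoints_3d(cfg$compare_with, skeleton = skeleton)
    oart <- analyze_series(other, file.path(outdir, "system_b"), event_hz,
                           kin_hz, logmsg)
    cmp <- compare_cycle_sets(artifacts, oart, alpha = alpha, seed = seed)
    if (!is.null(cmp)) write_comparison(cmp, file.path(outdir, "comparison"))
    else logmsg("comparison skipped: too few paired cycles")
  }
  logmsg("done")
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
}

# events + parameters + angles + TRC for one record
analyze_series <- function(series, outdir, event_hz, kin_hz, logmsg) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cycles <- segment_cycles(series, event_cutoff_hz = event_hz)
  logmsg("detected ", length(cycles), " gait cycles")
  events_table(cycles, series$fps, file.path(outdir, "events.csv"))
  params <- compute_params_all(series, cycles, cutoff_hz = kin_hz)
  utils::write.csv(params, file.path(outdir, "params.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_params(params),
                   file.path(outdir, "params_summary.csv"), row.names = FALSE)
  angles <- compute_joint_angles_all(series, cycles, cutoff_hz = kin_hz)
  angles_table(angles, file.path(outdir, "angles.csv"))
  filled <- interpolate_gaps(series, max_gap_frames = series$frames)
  if (!any(filled$missing)) {
    write_trc(filled, file.path(outdir, "trajectories.trc"))
  }
  list(series = series, cycles = cycles, params = params, angles = angles)
}

# pair two systems' analyses cycle-by-cycle and run the comparison
compare_cycle_sets <- function(a, b, alpha = 0.05, seed = 1L) {
  n <- min(nrow(a$params), nrow(b$params), length(a$angles), length(b$angles))
  if (n < 3L) return(NULL)
  cols <- c("stance_pct", "swing_pct", "stride_length_m", "stride_width_m",
            "stride_time_s", "speed_m_s")
  pa <- a$params[seq_len(n), cols]
  pb <- b$params[seq_len(n), cols]
  angle_names <- names(a$angles[[1]]$curves)
  aa <- lapply(stats::setNames(nm = angle_names), function(nm) {
    t(vapply(a$angles[seq_len(n)], function(x) x$curves[[nm]], numeric(101)))
  })
  ab <- lapply(stats::setNames(nm = angle_names), function(nm) {
    t(vapply(b$angles[seq_len(n)], function(x) x$curves[[nm]], numeric(101)))
  })
  compare_systems(pa, pb, aa, ab, alpha = alpha, seed = seed)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (emit synthetic 2D/3D/calibration/ground-truth
#' files), `triangulate`, `events`, `params`, `angles`, `eval` (pose
#' metrics against a reference), `compare`, and `run` (full pipeline from
#' a config). Invoke through the `inst/exec/gaitless` script or directly:
#' `Rscript -e 'gaitless::gait_cli()' run --config cfg.json`.
#'
#' Exit codes: 0 success, 2 configuration error, 3 data error.
#'
#' @param args character vector; defaults to `commandArgs(TRUE)`.
#' @return Integer exit code, invisibly.
#' @export
gait_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gaitless <command> [options]",
    "commands:",
    "  simulate    --out DIR [--seed N] [--duration S] [--noise-px SD]",
    "  run         --config FILE",
    "  triangulate --calibration FILE --out FILE view1.csv view2.csv ...",
    "  events      --in 3d.csv --out FILE",
    "  params      --in 3d.csv --out FILE",
    "  angles      --in 3d.csv --out FILE",
    "  eval        --estimate 3d.csv --truth 3d.csv",
    "  compare     --a 3d.csv --b 3d.csv --out DIR [--alpha A] [--seed N]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  code <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(opts),
      run = { run_pipeline(opts$config %||% stop_cfg("--config required")); 0L },
      triangulate = cli_triangulate(opts),
      events = cli_events(opts),
      params = cli_params(opts),
      angles = cli_angles(opts),
      eval = cli_eval(opts),
      compare = cli_compare(opts),
      { message("unknown command '", cmd, "'\n", usage); 2L })
  },
  gait_config_error = function(e) { message("config error: ", e$message); 2L },
  error = function(e) { message("error: ", e$message); 3L })
  invisible(code)
}

stop_cfg <- function(msg) {
  stop(structure(class = c("gait_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

parse_cli_opts <- function(args) {
  opts <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

cli_simulate <- function(opts) {
  out <- opts$out %||% stop_cfg("--out required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- gait_sim_config(
    seed = as.integer(opts$seed %||% 1L),
    duration_s = as.numeric(opts$duration %||% 5),
    pixel_noise_sd_px = as.numeric(opts$noise_px %||% 0))
  sim <- simulate_walk(cfg)
  write_keypoints_3d(sim$series, file.path(out, "simulated_3d.csv"))
  cams <- default_camera_rig()
  write_calibration(cams, file.path(out, "calibration.json"))
  views <- render_views(sim$series, cams,
                        pixel_noise_sd_px = cfg$pixel_noise_sd_px,
                        missing_rate = cfg$missing_rate, seed = cfg$seed)
  for (v in views) {
    write_keypoints_2d(v, file.path(out, paste0(v$camera_id, "_2d.csv")))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(heel_strike_frames = truth$heel_strike_frames,
         toe_off_frames = truth$toe_off_frames,
         params = truth$params,
         angle_profiles = truth$angle_profiles),
    file.path(out, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  0L
}

cli_triangulate <- function(opts) {
  calib <- opts$calibration %||% stop_cfg("--calibration required")
  out <- opts$out %||% stop_cfg("--out required")
  if (length(opts$positional) < 2L) stop_cfg("need >= 2 view CSVs")
  cams <- read_calibration(calib)
  views <- lapply(opts$positional, read_keypoints_2d, skeleton = "h36m21")
  series <- triangulate_series(views, cams)
  write_keypoints_3d(series, out)
  0L
}

cli_events <- function(opts) {
  s <- read_keypoints_3d(opts$`in` %||% stop_cfg("--in required"),
                         skeleton = "h36m21")
  cycles <- segment_cycles(s)
  events_table(cycles, s$fps, opts$out %||% stop_cfg("--out required"))
  0L
}

cli_params <- function(opts) {
  s <- read_keypoints_3d(opts$`in` %||% stop_cfg("--in required"),
                         skeleton = "h36m21")
  params <- compute_params_all(s)
  utils::write.csv(params, opts$out %||% stop_cfg("--out required"),
                   row.names = FALSE)
  0L
}

cli_angles <- function(opts) {
  s <- read_keypoints_3d(opts$`in` %||% stop_cfg("--in required"),
                         skeleton = "h36m21")
  angles <- compute_joint_angles_all(s)
  angles_table(angles, opts$out %||% stop_cfg("--out required"))
  0L
}

cli_eval <- function(opts) {
  est <- read_keypoints_3d(opts$estimate %||% stop_cfg("--estimate required"),
                           skeleton = "h36m21")
  tru <- read_keypoints_3d(opts$truth %||% stop_cfg("--truth required"),
                           skeleton = "h36m21")
  err <- mpjpe(est$coords, tru$coords, per_keypoint = TRUE)
  cat(sprintf("MPJPE: %.3f mm\n", 1000 * err$overall))
  for (nm in names(err$per_keypoint)) {
    cat(sprintf("  %-16s %.3f mm\n", nm, 1000 * err$per_keypoint[nm]))
  }
  0L
}

cli_compare <- function(opts) {
  sa <- read_keypoints_3d(opts$a %||% stop_cfg("--a required"),
                          skeleton = "h36m21")
  sb <- read_keypoints_3d(opts$b %||% stop_cfg("--b required"),
                          skeleton = "h36m21")
  out <- opts$out %||% stop_cfg("--out required")
  arta <- analyze_series(sa, file.path(out, "system_a"), 3, 12,
                         function(...) invisible(NULL))
  artb <- analyze_series(sb, file.path(out, "system_b"), 3, 12,
                         function(...) invisible(NULL))
  cmp <- compare_cycle_sets(arta, artb,
                            alpha = as.numeric(opts$alpha %||% 0.05),
                            seed = as.integer(opts$seed %||% 1L))
  if (is.null(cmp)) stop("too few paired cycles to compare")
  write_comparison(cmp, file.path(out, "comparison"))
  0L
}
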