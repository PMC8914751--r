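#' Walking direction of a record
#'
#' The progression direction is the first principal axis of the horizontal
#' pelvis-root displacement, signed along the net motion; the lateral axis
#' is vertical x progression. All width/length decompositions downstream
#' are defined against these axes, which makes the parameters invariant to
#' rotations of the capture volume about the vertical.
#'
#' @param series a `kps3d` with a pelvis-root role.
#' @param window optional 1-based frame range `c(from, to)`; default whole
#'   record.
#' @param min_displacement_m minimum net horizontal displacement (default
#'   0.5 m).
#' @return List with unit 3-vectors `progression` and `lateral` (both
#'   horizontal) and `vertical`.
#' @export
walking_direction <- function(series, window = NULL,
                              min_displacement_m = 0.5) {
  stopifnot(inherits(series, "kps3d"))
  root <- kp_traj(series, "pelvis_root")
  if (!is.null(window)) root <- root[window[1]:window[2], , drop = FALSE]
  root <- root[stats::complete.cases(root), , drop = FALSE]
  if (nrow(root) < 2L) stop("no progression: too few pelvis samples")
  vi <- vertical_index(series)
  hz <- setdiff(1:3, vi)
  H <- root[, hz, drop = FALSE]
  net <- H[nrow(H), ] - H[1, ]
  if (sqrt(sum(net^2)) < min_displacement_m) {
    stop("no progression: net horizontal displacement below ",
         min_displacement_m, " m")
  }
  Hc <- sweep(H, 2, colMeans(H))
  pc <- svd(Hc, nu = 0, nv = 1)$v[, 1]
  if (sum(pc * net) < 0) pc <- -pc
  prog <- numeric(3); prog[hz] <- pc
  up <- numeric(3); up[vi] <- 1
  lat <- c(up[2] * prog[3] - up[3] * prog[2],
           up[3] * prog[1] - up[1] * prog[3],
           up[1] * prog[2] - up[2] * prog[1])
  list(progression = prog, lateral = lat / sqrt(sum(lat^2)), vertical = up)
}

#' Spatio-temporal gait parameters of one cycle
#'
#' Computes the six per-cycle parameters from heel and pelvis trajectories
#' (12 Hz low-pass filtered before measurement): stride length (horizontal
#' displacement of the ipsilateral heel between consecutive strikes),
#' stride time, stance and swing percentages (from the cycle's event
#' fractions; they sum to 100 exactly), stride (step) width (mean absolute
#' lateral separation of the two heels across the cycle's frames), and
#' speed (mean speed of the pelvis-root keypoint, the center-of-mass
#' proxy, over the cycle).
#'
#' @param series a `kps3d` with heel and pelvis-root roles bound.
#' @param cycle a [gait_cycle()].
#' @param cutoff_hz kinematics low-pass cutoff (default 12 Hz).
#' @param prefiltered set TRUE when `series` is already filtered.
#' @return A one-row data.frame of class `gait_params` with columns side,
#'   start_frame, end_frame, central, stride_length_m, stride_time_s,
#'   stance_pct, swing_pct, stride_width_m, speed_m_s.
#' @export
compute_params <- function(series, cycle, cutoff_hz = 12,
                           prefiltered = FALSE) {
  stopifnot(inherits(series, "kps3d"), inherits(cycle, "gait_cycle"))
  fser <- prepare_kinematics(series, cutoff_hz, prefiltered)
  i0 <- cycle$start_frame + 1L        # to 1-based
  i1 <- cycle$end_frame + 1L
  stopifnot(i0 >= 1, i1 <= fser$frames)
  dir <- walking_direction(fser)
  vi <- vertical_index(fser)
  hz <- setdiff(1:3, vi)

  heel <- kp_traj(fser, paste0(cycle$side, "_heel"))
  dvec <- heel[i1, ] - heel[i0, ]
  stride_length <- sqrt(sum(dvec[hz]^2))

  stride_time <- (cycle$end_frame - cycle$start_frame) / fser$fps

  other <- if (cycle$side == "left") "right" else "left"
  width <- NA_real_
  oheel <- tryCatch(kp_traj(fser, paste0(other, "_heel")),
                    error = function(e) NULL)
  if (!is.null(oheel)) {
    sep <- heel[i0:i1, , drop = FALSE] - oheel[i0:i1, , drop = FALSE]
    lat <- abs(sep %*% dir$lateral)
    if (all(is.na(lat))) width <- NA_real_
    else width <- mean(lat, na.rm = TRUE)
  }

  root <- kp_traj(fser, "pelvis_root")
  rv <- velocity(root[i0:i1, , drop = FALSE], fs = fser$fps)
  speed <- mean(sqrt(rowSums(rv^2)))

  out <- data.frame(side = cycle$side,
                    start_frame = cycle$start_frame,
                    end_frame = cycle$end_frame,
                    central = cycle$central,
                    stride_length_m = stride_length,
                    stride_time_s = stride_time,
                    stance_pct = 100 * cycle$stance_fraction,
                    swing_pct = 100 * cycle$swing_fraction,
                    stride_width_m = width,
                    speed_m_s = speed)
  class(out) <- c("gait_params", "data.frame")
  out
}

# interpolate + 12 Hz filter once; memoized by attribute to avoid repeated
# filtering when computing many cycles of the same record
prepare_kinematics <- function(series, cutoff_hz, prefiltered) {
  if (prefiltered) return(series)
  s <- interpolate_gaps(series)
  if (any(s$missing)) {
    # long gaps survive interpolation; hold them to keep the filter defined
    for (k in seq_along(s$keypoints)) {
      if (any(s$missing[, k])) {
        s$coords[, k, ] <- interp_gaps_matrix(s$coords[, k, , drop = TRUE],
                                              s$keypoints[k])
      }
    }
    s <- keypoint_series_3d(s$coords, s$fps, keypoints = s$keypoints,
                            vertical_axis = s$vertical_axis,
                            skeleton = s$skeleton)
  }
  butterworth_lowpass(s, cutoff_hz)
}

#' Parameters for every cycle of a record
#'
#' @param series a `kps3d`.
#' @param cycles list of [gait_cycle()]; defaults to [segment_cycles()].
#' @param cutoff_hz kinematics low-pass cutoff (default 12 Hz).
#' @return data.frame, one row per cycle.
#' @export
compute_params_all <- function(series, cycles = NULL, cutoff_hz = 12) {
  if (is.null(cycles)) cycles <- segment_cycles(series)
  if (!length(cycles)) {
    return(data.frame(side = character(), start_frame = integer(),
                      end_frame = integer(), central = logical(),
                      stride_length_m = numeric(), stride_time_s = numeric(),
                      stance_pct = numeric(), swing_pct = numeric(),
                      stride_width_m = numeric(), speed_m_s = numeric()))
  }
  fser <- prepare_kinematics(series, cutoff_hz, FALSE)
  do.call(rbind, lapply(cycles, function(cy) {
    compute_params(fser, cy, prefiltered = TRUE)
  }))
}

#' Summarize per-cycle parameters (mean and SD per group)
#'
#' Produces the conventional summary-table layout: mean +/- SD of each of
#' the six parameters, overall or per grouping column (e.g. subject).
#'
#' @param params data.frame of per-cycle rows (from [compute_params_all()]
#'   or concatenated across subjects).
#' @param by optional name of a grouping column.
#' @return data.frame with one row per group (plus `n_cycles`), columns
#'   `<param>_mean` and `<param>_sd`.
#' @export
summarize_params <- function(params, by = NULL) {
  cols <- c("stance_pct", "swing_pct", "stride_length_m", "stride_width_m",
            "stride_time_s", "speed_m_s")
  groups <- if (is.null(by)) list(all = seq_len(nrow(params)))
            else split(seq_len(nrow(params)), params[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    row <- data.frame(group = g, n_cycles = length(idx))
    for (cc in cols) {
      row[[paste0(cc, "_mean")]] <- mean(params[[cc]][idx], na.rm = TRUE)
      row[[paste0(cc, "_sd")]] <- stats::sd(params[[cc]][idx], na.rm = TRUE)
    }
    row
  }))
  if (!is.null(by)) names(out)[1] <- by
  out
}
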