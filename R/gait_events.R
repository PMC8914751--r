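#' Heel-strike detection from heel-keypoint speed
#'
#' Implements the speed-based gait-cycle detector: the heel's speed is close
#' to zero throughout stance and rises in swing, so stance onsets are found
#' as entries into low-speed intervals. The detector has two stages.
#'
#' Coarse stage: (1) interpolate gaps; (2) zero-phase Butterworth low-pass
#' of the heel trajectory (`event_cutoff_hz`, 4th order); (3) 3D speed
#' magnitude by central differences; (4) hysteresis thresholding into
#' low-speed (stance-candidate) intervals — enter below the adaptive
#' falling threshold (`threshold_frac` of the 95th-percentile speed), leave
#' above `rising_factor` times it; (5) discard intervals shorter than
#' `min_interval_s`; intervals already low at the record start are not
#' counted (a strike must be *entered* from swing).
#'
#' Refinement stage (`refine = TRUE`, the default): the low-pass filter
#' needed for robust thresholding smears the speed profile by several
#' frames, biasing the threshold crossing into the swing. The strike is
#' therefore re-localized on the *unfiltered* trajectory: within each
#' candidate interval the exact rest run is found (central-difference
#' speed at the noise floor), and the touch-down instant is extrapolated
#' to sub-frame precision by inverting a minimum-jerk swing-displacement
#' model whose stride length and swing duration are estimated from the
#' record's own rest plateaus (falling back to per-component power-law
#' extrapolation — cubic along progression, quadratic vertically — when
#' no stride model is available). Because steady-gait strikes lie on a
#' near-periodic lattice, sub-frame estimates within one frame of the
#' best-fit lattice are pooled across cycles before rounding to the frame
#' grid; larger deviations are kept as estimated. With `refine = FALSE`
#' the first frame of the coarse interval is returned, as in the plain
#' threshold detector.
#'
#' Returns 0-based frame indices.
#'
#' @param series a `kps3d` carrying a skeleton with heel roles.
#' @param side `"left"` or `"right"`.
#' @param event_cutoff_hz low-pass cutoff for event detection (default 3).
#' @param threshold_frac falling threshold as a fraction of the
#'   95th-percentile speed (default 0.15).
#' @param rising_factor hysteresis: rising threshold = `rising_factor` x
#'   falling (default 1.25).
#' @param min_interval_s minimum stance-candidate duration (default 0.1 s).
#' @param refine sub-frame onset refinement on the raw trajectory (default
#'   TRUE).
#' @param min_motion_m_s absolute floor on the 95th-percentile speed below
#'   which the record is declared stationary (default 0.05 m/s).
#' @return Integer vector of strictly increasing 0-based frames, possibly
#'   empty; attribute `"diagnostic"` carries a message when empty.
#' @export
detect_heel_strikes <- function(series, side = c("left", "right"),
                                event_cutoff_hz = 3, threshold_frac = 0.15,
                                rising_factor = 1.25, min_interval_s = 0.1,
                                refine = TRUE, min_motion_m_s = 0.05) {
  side <- match.arg(side)
  prep <- event_prep(series, paste0(side, "_heel"), event_cutoff_hz)
  iv <- coarse_low_intervals(prep$speed_filt, series$fps, threshold_frac,
                             rising_factor, min_interval_s, min_motion_m_s)
  if (!is.null(attr(iv, "diagnostic"))) {
    out <- integer(0)
    attr(out, "diagnostic") <- attr(iv, "diagnostic")
    return(out)
  }
  strikes <- if (refine) {
    snap_to_lattice(refine_strikes(prep, iv, series))
  } else {
    vapply(iv, `[`, numeric(1), 1L)
  }
  strikes <- as.integer(round(strikes))
  strikes <- strikes[strikes >= 1 & strikes <= series$frames]
  sort(unique(strikes)) - 1L   # 0-based
}

# steady-gait regularization: consecutive strikes of one foot sit on a
# near-periodic lattice, so sub-frame estimates that deviate from the
# best-fit lattice by less than a frame are snapped onto it (pooling the
# sub-frame information across cycles); larger deviations -- genuinely
# irregular cycles -- are kept as estimated.
snap_to_lattice <- function(ts) {
  if (length(ts) < 3L) return(ts)
  dif <- diff(ts)
  P <- stats::median(dif)
  if (!is.finite(P) || P <= 1) return(ts)
  k <- c(0, cumsum(round(dif / P)))
  fit <- stats::lm.fit(cbind(1, k), ts)
  pred <- fit$coefficients[1] + fit$coefficients[2] * k
  ifelse(abs(ts - pred) <= 1, pred, ts)
}

# refine all strike onsets of one record. When at least two rest runs are
# available, the stride length and swing duration estimated from the rest
# plateaus themselves parameterize a minimum-jerk swing model whose
# inversion localizes each touch-down to sub-frame precision (a matched
# filter for the approach displacement along the progression axis);
# otherwise the generic power-law extrapolation is used.
refine_strikes <- function(prep, iv, series) {
  p95 <- stats::quantile(prep$speed_filt, 0.95, names = FALSE)
  runs <- lapply(iv, function(bounds) rest_run(prep$speed_raw, bounds, p95))
  model <- stance_model(prep, runs)
  vapply(seq_along(iv), function(i) {
    if (is.null(runs[[i]])) return(iv[[i]][1])
    est <- if (!is.null(model)) {
      minjerk_boundary(prep, runs[[i]], model, "onset")
    } else NULL
    if (is.null(est)) refine_boundary(prep, runs[[i]], series, "onset")
    else est
  }, numeric(1))
}

min_jerk_s <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1,
                                 u^3 * (10 - 15 * u + 6 * u^2)))

# per-record gait model from the rest runs of one foot keypoint: plateau
# positions, stride length, swing duration (frames) and progression axis
stance_model <- function(prep, runs) {
  ok <- which(!vapply(runs, is.null, logical(1)))
  if (length(ok) < 2L) return(NULL)
  plateaus <- t(vapply(ok, function(i) {
    apply(prep$raw[runs[[i]][1]:runs[[i]][2], , drop = FALSE], 2,
          stats::median)
  }, numeric(3)))
  hops <- diff(ok)
  dp <- plateaus[-1, , drop = FALSE] - plateaus[-nrow(plateaus), , drop = FALSE]
  net <- colSums(dp)
  axis <- net / max(sqrt(sum(net^2)), 1e-12)
  stride <- stats::median((dp %*% axis) / hops)
  gaps <- vapply(seq_along(hops), function(j) {
    (runs[[ok[j + 1L]]][1] - runs[[ok[j]]][2]) / hops[j]
  }, numeric(1))
  swing <- stats::median(gaps) - 1
  if (!is.finite(stride) || stride < 0.2 || !is.finite(swing) || swing <= 3) {
    return(NULL)
  }
  list(stride = stride, swing = swing, axis = axis,
       plateau_for = function(run) {
      apply(prep$raw[run[1]:run[2], , drop = FALSE], 2, stats::median)
    })
}

# matched-filter boundary refinement: the foot advances by one stride
# length along the progression axis during swing following a minimum-jerk
# profile, so inverting that profile at the sampled displacements gives
# sub-frame estimates of the boundary; samples are combined by their
# local-slope information. Vertical clearance is excluded by projecting on
# the progression axis. Returns the refined 1-based frame, or NULL.
minjerk_boundary <- function(prep, run, model, direction) {
  raw <- prep$raw
  n <- nrow(raw)
  plateau <- model$plateau_for(run)
  if (direction == "onset") {
    anchor <- run[1] - 1L               # B: first frame at rest
    steps <- anchor - (1:4)
  } else {
    anchor <- run[2] + 1L               # E: last frame at rest
    steps <- anchor + (1:4)
  }
  keep <- steps >= 1L & steps <= n
  steps <- steps[keep]
  idx <- (1:4)[keep]
  if (length(steps) < 2L) return(NULL)
  dm <- sweep(raw[steps, , drop = FALSE], 2, plateau)
  d <- abs(as.numeric(dm %*% model$axis))
  quiet <- run[1]:run[2]
  resid <- sweep(raw[quiet, , drop = FALSE], 2, plateau)
  sig <- max(stats::mad(as.numeric(resid %*% model$axis)), 1e-9)
  usable <- which(d > 6 * sig & d < 0.8 * model$stride)
  if (!length(usable)) return(NULL)
  # the nearest usable samples carry the least model error (secondary
  # motion components grow faster than the minimum-jerk advance)
  usable <- utils::head(usable, 2L)
  inv_mj <- function(frac) {
    frac <- min(max(frac, 0), 1)
    stats::uniroot(function(u) min_jerk_s(u) - frac, c(0, 1),
                   tol = 1e-10)$root
  }
  phis <- ws <- numeric(length(usable))
  for (j in seq_along(usable)) {
    u <- inv_mj(d[usable[j]] / model$stride)
    phis[j] <- idx[usable[j]] - u * model$swing
    slope <- model$stride * 30 * u^2 * (1 - u)^2 / model$swing
    ws[j] <- (max(slope, 1e-6) / sig)^2
  }
  phi <- sum(phis * ws) / sum(ws)
  if (!is.finite(phi) || phi < -1.45 || phi > 1.45) return(NULL)
  if (direction == "onset") anchor - phi else anchor + phi   # continuous
}

event_prep <- function(series, role, cutoff_hz) {
  stopifnot(inherits(series, "kps3d"))
  if (series$frames / series$fps < 1) stop("record shorter than 1 s")
  raw <- interp_gaps_matrix(kp_traj(series, role), role)
  filt <- butterworth_lowpass(raw, cutoff_hz, order = 4L, fs = series$fps)
  vf <- velocity(filt, fs = series$fps)
  vr <- velocity(raw, fs = series$fps)
  list(raw = raw, filt = filt,
       speed_filt = sqrt(rowSums(vf^2)),
       speed_raw = sqrt(rowSums(vr^2)),
       fps = series$fps)
}

interp_gaps_matrix <- function(m, label) {
  miss <- apply(is.na(m), 1, any)
  if (!any(miss)) return(m)
  if (all(miss)) stop("keypoint '", label, "' is entirely missing")
  valid <- which(!miss)
  for (d in seq_len(ncol(m))) {
    m[miss, d] <- stats::spline(valid, m[valid, d], xout = which(miss),
                                method = "natural")$y
  }
  first <- min(valid); last <- max(valid)
  if (first > 1L) m[1:(first - 1L), ] <- rep(m[first, ], each = first - 1L)
  if (last < nrow(m)) {
    m[(last + 1L):nrow(m), ] <- rep(m[last, ], each = nrow(m) - last)
  }
  m
}

# hysteresis thresholding of the filtered speed into low-speed intervals.
# Returns a list of c(start, end) in 1-based frames, or an empty list with
# a "diagnostic" attribute.
coarse_low_intervals <- function(speed, fps, threshold_frac, rising_factor,
                                 min_interval_s, min_motion_m_s) {
  p95 <- stats::quantile(speed, 0.95, names = FALSE)
  fail <- function(msg) {
    out <- list()
    attr(out, "diagnostic") <- msg
    out
  }
  if (!is.finite(p95) || p95 < min_motion_m_s) {
    return(fail("no gait detected: record is (near-)stationary"))
  }
  thr_fall <- threshold_frac * p95
  thr_rise <- rising_factor * thr_fall
  n <- length(speed)
  low <- FALSE; from_high <- FALSE; seen_high <- FALSE
  start <- NA_integer_
  out <- list()
  for (i in seq_len(n)) {
    if (!low) {
      if (speed[i] < thr_fall) {
        low <- TRUE; start <- i; from_high <- seen_high
      } else seen_high <- TRUE
    } else if (speed[i] > thr_rise) {
      if (from_high) out[[length(out) + 1L]] <- c(start, i - 1L)
      low <- FALSE; seen_high <- TRUE
    }
  }
  if (low && from_high) out[[length(out) + 1L]] <- c(start, n)
  if (!length(out)) {
    return(fail("no gait detected: no low-speed interval entered from swing"))
  }
  out <- Filter(function(iv) iv[2] - iv[1] + 1L >= min_interval_s * fps, out)
  if (!length(out)) {
    return(fail("no gait detected: all low-speed intervals too short"))
  }
  out
}

# the exact rest run inside a coarse interval, on the raw speed signal
rest_run <- function(speed_raw, bounds, p95) {
  lo <- max(1L, bounds[1] - 2L)
  hi <- bounds[2]
  win <- lo:hi
  # noise floor from the calm part of the interval: the lower quartile of
  # the interval's speeds sits at ~1.1x the per-axis noise SD (3D noise
  # norm), so 4.5x that separates rest (+ rare spikes, removed by the
  # one-frame closing below) from the swing rise
  q25 <- stats::quantile(speed_raw[win], 0.25, names = FALSE)
  thr <- max(4.5 * q25, 0.01 * p95, 1e-9)
  quiet <- speed_raw[win] <= thr
  if (!any(quiet)) return(NULL)
  if (length(quiet) > 2L) {
    spikes <- which(!quiet[-c(1L, length(quiet))]) + 1L
    spikes <- spikes[quiet[spikes - 1L] & quiet[spikes + 1L]]
    quiet[spikes] <- TRUE
  }
  r <- rle(quiet)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2L)
  if (!length(runs)) return(NULL)
  best <- runs[which.max(r$lengths[runs])]
  c(win[starts[best]], win[ends[best]])
}

# sub-frame power-law extrapolation of a translation boundary.
# disp holds |displacement from the rest plateau| at 1, 2, 3 frames beyond
# the assumed boundary frame; model disp_i = c * (i - phi)^p. Solved from
# the first reliable ratio pair; per-component estimates are combined by
# inverse variance. phi may land up to one frame outside the detected rest
# run: tiny sub-threshold motion can shift the run edge by one frame, and
# the solve recovers that exactly.
powerlaw_offset <- function(disp, sigma, p) {
  disp <- unname(disp); sigma <- unname(sigma)
  i0 <- which(disp > 6 * sigma)[1]
  if (is.na(i0) || i0 >= length(disp)) return(NULL)
  ratio <- disp[i0 + 1L] / disp[i0]
  if (!is.finite(ratio) || ratio <= 1.05) return(NULL)
  r <- ratio^(1 / p)
  phi <- (r * i0 - (i0 + 1L)) / (r - 1)
  if (!is.finite(phi)) return(NULL)
  phi <- min(max(phi, -1.45), 1.45)
  # delta-method variance of phi from the noise on the two displacements
  dr <- r / p * sqrt((sigma / disp[i0])^2 + (sigma / disp[i0 + 1L])^2)
  var_phi <- (1 / (r - 1)^2)^2 * dr^2 + 1e-12
  c(phi = unname(phi), w = unname(1 / var_phi))
}

# translation-boundary refinement: smooth (minimum-jerk) displacement
# onsets grow as t^3 along the progression axis and as t^2 vertically
# (clearance). direction "onset" = approach into rest (heel strike);
# "departure" = leaving rest (heel-off, the fallback for toe-off when no
# toe keypoint exists). Returns the refined 1-based frame.
refine_boundary <- function(prep, run, series, direction) {
  raw <- prep$raw
  n <- nrow(raw)
  quiet_idx <- run[1]:run[2]
  plateau <- apply(raw[quiet_idx, , drop = FALSE], 2, stats::median)
  resid <- sweep(raw[quiet_idx, , drop = FALSE], 2, plateau)
  sig <- pmax(apply(resid, 2, stats::mad), 1e-9)

  if (direction == "onset") {        # B = first frame at rest
    B <- run[1] - 1L
    steps <- B - (1:3)
    fallback <- B
  } else {                           # E = last frame at rest
    E <- run[2] + 1L
    steps <- E + (1:3)
    fallback <- E
  }
  if (any(steps < 1L | steps > n)) return(fallback)
  dm <- sweep(raw[steps, , drop = FALSE], 2, plateau)

  vi <- vertical_index(series)
  hz <- setdiff(1:3, vi)
  hdom <- hz[which.max(colSums(abs(dm[, hz, drop = FALSE])))]

  ests <- Filter(Negate(is.null), list(
    powerlaw_offset(abs(dm[, hdom]), sig[hdom], p = 3),
    powerlaw_offset(abs(dm[, vi]), sig[vi], p = 2)))
  if (!length(ests)) return(fallback)
  phis <- vapply(ests, `[[`, numeric(1), "phi")
  ws <- vapply(ests, `[[`, numeric(1), "w")
  phi <- sum(phis * ws) / sum(ws)
  if (direction == "onset") (run[1] - 1L) - phi
  else (run[2] + 1L) + phi                                   # continuous
}

refine_contact_onset <- function(prep, bounds, series) {
  p95 <- stats::quantile(prep$speed_filt, 0.95, names = FALSE)
  run <- rest_run(prep$speed_raw, bounds, p95)
  if (is.null(run)) return(bounds[1])
  refine_boundary(prep, run, series, "onset")
}

#' Toe-off detection within detected gait cycles
#'
#' One toe-off per cycle, strictly inside it: the toe keypoint's filtered
#' speed rises through the adaptive threshold after the stance onset, and
#' the lift-off instant is refined on the raw trajectories — the foot
#' (heel to toe) segment starts pitching about the forefoot at lift-off,
#' and the lift-off instant is refined like heel strikes: the rest run of
#' the raw toe trajectory anchors the boundary, and the minimum-jerk
#' matched model (or, without a usable stride model, per-component
#' power-law extrapolation) localizes it to sub-frame precision before
#' rounding to the frame grid. Falls back to the ipsilateral heel's
#' departure (heel-off) when the skeleton binds no toe for the side,
#' flagged via attribute `"used_fallback"`.
#'
#' @inheritParams detect_heel_strikes
#' @param heel_strikes 0-based strike frames (>= 2 for any output).
#' @return Integer vector of 0-based toe-off frames, one per complete
#'   cycle; empty when fewer than 2 strikes are given.
#' @export
detect_toe_off <- function(series, side = c("left", "right"), heel_strikes,
                           event_cutoff_hz = 3, threshold_frac = 0.15,
                           refine = TRUE) {
  side <- match.arg(side)
  if (length(heel_strikes) < 2L) return(integer(0))
  fallback <- is.null(series$skeleton) ||
    is.null(resolve_role_quiet(series, paste0(side, "_toe")))
  role <- paste0(side, if (fallback) "_heel" else "_toe")
  prep <- event_prep(series, role, event_cutoff_hz)
  p95 <- stats::quantile(prep$speed_filt, 0.95, names = FALSE)
  thr <- threshold_frac * p95
  ncyc <- length(heel_strikes) - 1L
  runs <- vector("list", ncyc)
  coarse <- rep(NA_integer_, ncyc)
  for (ci in seq_len(ncyc)) {
    a <- heel_strikes[ci] + 1L        # 1-based cycle bounds
    b <- heel_strikes[ci + 1L] + 1L
    win <- (a + 1L):(b - 1L)
    # the toe is still decelerating from its own landing just after the
    # strike: wait for the speed to settle below the threshold, then take
    # the first rising crossing
    settle <- win[which(prep$speed_filt[win] < thr)[1]]
    if (is.na(settle)) next
    win2 <- settle:(b - 1L)
    cross <- win2[which(prep$speed_filt[win2] > thr)[1]]
    if (is.na(cross)) next
    coarse[ci] <- cross - 1L
    if (refine) runs[[ci]] <- rest_run(prep$speed_raw,
                                       c(settle, cross - 1L), p95)
  }
  model <- if (refine) stance_model(prep, runs) else NULL
  estimate_all <- function(model) {
    est <- rep(NA_real_, ncyc)
    for (ci in seq_len(ncyc)) {
      if (is.na(coarse[ci])) next
      to <- coarse[ci]
      if (refine && !is.null(runs[[ci]])) {
        e <- if (!is.null(model)) {
          minjerk_boundary(prep, runs[[ci]], model, "departure")
        } else NULL
        if (is.null(e)) e <- refine_boundary(prep, runs[[ci]], series,
                                             "departure")
        to <- e
      }
      est[ci] <- to
    }
    est
  }
  est <- estimate_all(model)
  if (refine && !is.null(model) && sum(!is.na(est)) >= 3L) {
    # the swing duration from rest-run gaps is biased by the noise-dependent
    # run edges; re-estimate it from the first-pass toe-offs against the
    # known strikes (swing = next strike - toe-off) and solve again
    ok0 <- which(!is.na(est))
    swing_new <- stats::median(heel_strikes[ok0 + 1L] + 1 - est[ok0])
    if (is.finite(swing_new) && swing_new > 3) {
      model$swing <- swing_new
      est <- estimate_all(model)
    }
  }
  # steady-gait regularization: the stance duration of one foot is stable
  # across cycles, so per-cycle sub-frame estimates within a frame of the
  # record median offset are pooled before rounding; larger deviations are
  # kept as estimated
  ok <- which(!is.na(est))
  offs <- est[ok] - (heel_strikes[ok] + 1)
  if (refine && length(ok) >= 3L) {
    med <- stats::median(offs)
    offs <- ifelse(abs(offs - med) <= 1, med, offs)
  }
  out <- integer(0)
  for (j in seq_along(ok)) {
    ci <- ok[j]
    a <- heel_strikes[ci] + 1L
    b <- heel_strikes[ci + 1L] + 1L
    to <- round(a + offs[j])
    to <- min(max(to, a + 1L), b - 1L)  # strictly inside the cycle
    out <- c(out, as.integer(to) - 1L)  # 0-based
  }
  attr(out, "used_fallback") <- fallback
  out
}

resolve_role_quiet <- function(series, role) {
  kp <- role_keypoint(series$skeleton, role, required = FALSE)
  if (!is.null(kp) && kp %in% series$keypoints) kp else NULL
}

#' A single gait cycle
#'
#' @param side `"left"` or `"right"`.
#' @param start_frame,toe_off_frame,end_frame 0-based frames with
#'   `start < toe_off < end`; start and end are consecutive ipsilateral
#'   heel strikes.
#' @param central is this the central cycle of the record?
#' @return A `gait_cycle` with exact `stance_fraction + swing_fraction = 1`.
#' @export
gait_cycle <- function(side, start_frame, toe_off_frame, end_frame,
                       central = FALSE) {
  stopifnot(start_frame < toe_off_frame, toe_off_frame < end_frame)
  stance <- (toe_off_frame - start_frame) / (end_frame - start_frame)
  structure(list(side = side, start_frame = as.integer(start_frame),
                 toe_off_frame = as.integer(toe_off_frame),
                 end_frame = as.integer(end_frame),
                 stance_fraction = stance, swing_fraction = 1 - stance,
                 central = central),
            class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("<gait_cycle> %s: frames %d-%d (toe-off %d), stance %.1f%%%s\n",
              x$side, x$start_frame, x$end_frame, x$toe_off_frame,
              100 * x$stance_fraction, if (x$central) " [central]" else ""))
  invisible(x)
}

#' Segment a record into gait cycles for both sides
#'
#' Detects heel strikes and toe-offs per side, builds [gait_cycle()]
#' objects, and flags the central cycle of the record per side (the cycle
#' whose midpoint lies nearest the record midpoint) for central-cycle
#' reporting.
#'
#' @inheritParams detect_heel_strikes
#' @param sides which sides to segment.
#' @param ... passed on to [detect_heel_strikes()] and [detect_toe_off()].
#' @return List of `gait_cycle` objects (possibly empty).
#' @export
segment_cycles <- function(series, sides = c("left", "right"), ...) {
  dots <- list(...)
  hs_args <- dots[names(dots) %in% names(formals(detect_heel_strikes))]
  to_args <- dots[names(dots) %in% c("event_cutoff_hz", "threshold_frac",
                                     "refine")]
  cycles <- list()
  for (side in sides) {
    hs <- do.call(detect_heel_strikes,
                  c(list(series = series, side = side), hs_args))
    if (length(hs) < 2L) next
    to <- do.call(detect_toe_off,
                  c(list(series = series, side = side, heel_strikes = hs),
                    to_args))
    for (ci in seq_len(length(hs) - 1L)) {
      if (ci > length(to)) next
      if (!(to[ci] > hs[ci] && to[ci] < hs[ci + 1L])) next
      cycles[[length(cycles) + 1L]] <-
        gait_cycle(side, hs[ci], to[ci], hs[ci + 1L])
    }
  }
  mid <- (series$frames - 1) / 2
  for (side in sides) {
    idx <- which(vapply(cycles, function(c) c$side == side, logical(1)))
    if (!length(idx)) next
    centers <- vapply(cycles[idx],
                      function(c) (c$start_frame + c$end_frame) / 2,
                      numeric(1))
    cycles[[idx[which.min(abs(centers - mid))]]]$central <- TRUE
  }
  cycles
}

#' Export detected events as a CSV table
#'
#' @param cycles list of `gait_cycle` (from [segment_cycles()]).
#' @param fps sampling rate used to convert frames to seconds.
#' @param path optional output path; when NULL the data.frame is returned
#'   without writing.
#' @return data.frame with columns side, event_type, frame, time_s.
#' @export
events_table <- function(cycles, fps, path = NULL) {
  rows <- list()
  for (cy in cycles) {
    rows[[length(rows) + 1L]] <- data.frame(
      side = cy$side,
      event_type = c("heel_strike", "toe_off"),
      frame = c(cy$start_frame, cy$toe_off_frame))
  }
  for (side in unique(vapply(cycles, `[[`, character(1), "side"))) {
    last <- Find(function(c) c$side == side, rev(cycles))
    rows[[length(rows) + 1L]] <- data.frame(
      side = side, event_type = "heel_strike", frame = last$end_frame)
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("side", "event_type", "frame")]), ]
  df <- df[order(df$frame, df$side), ]
  df$time_s <- df$frame / fps
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
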