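#' Kinematic walking simulator configuration
#'
#' The simulator is kinematic, not dynamic: every ground-truth quantity is
#' an exact function of the configuration, which is what makes closed-form
#' recovery tests possible downstream. The pelvis advances at constant mean
#' speed with small sinusoidal vertical/lateral oscillation; each heel is
#' anchored (exactly zero velocity) during its stance phase and advances by
#' one stride length during swing along a minimum-jerk horizontal path with
#' a smooth vertical clearance bump; the knee is solved by exact two-link
#' inverse kinematics between hip and ankle. Left and right are antiphase.
#' Default magnitudes bracket normal adult gait (stance 59.2%, stride
#' 1.35 m, stride time 1.13 s, step width 0.10 m).
#'
#' The stride period is quantized to `N = round(stride_time_s * fps)` frames
#' so that ground-truth events fall exactly on the frame grid; the effective
#' mean speed is `stride_length_m * fps / N`.
#'
#' @param stride_time_s stride (cycle) duration, seconds.
#' @param stride_length_m distance covered per cycle, meters.
#' @param duty_factor stance fraction of the cycle, in (0.4, 0.8).
#' @param step_width_m lateral separation between the heel lines, meters.
#' @param thigh_m,shank_m,foot_m segment lengths, meters.
#' @param pelvis_height_m mean pelvis-root height, meters.
#' @param fps sampling rate, Hz (>= 10).
#' @param duration_s record duration, seconds.
#' @param trajectory_noise_sd_m isotropic Gaussian noise added to every 3D
#'   sample after ground truth is recorded.
#' @param pixel_noise_sd_px default pixel noise for [render_views()].
#' @param missing_rate fraction of samples dropped at random, in [0, 1).
#' @param seed integer seed driving all simulator randomness (required).
#' @return A `gait_sim_config`.
#' @export
gait_sim_config <- function(stride_time_s = 1.13, stride_length_m = 1.35,
                            duty_factor = 0.592, step_width_m = 0.10,
                            thigh_m = 0.50, shank_m = 0.50, foot_m = 0.25,
                            pelvis_height_m = 0.88, fps = 30,
                            duration_s = 5, trajectory_noise_sd_m = 0,
                            pixel_noise_sd_px = 0, missing_rate = 0,
                            seed) {
  if (missing(seed)) stop("seed is a required field")
  stopifnot(duty_factor > 0.4, duty_factor < 0.8,
            stride_length_m > 0, stride_length_m < 2 * (thigh_m + shank_m),
            fps >= 10, stride_time_s > 0, duration_s > 0,
            thigh_m > 0, shank_m > 0, foot_m > 0, pelvis_height_m > 0,
            step_width_m >= 0, trajectory_noise_sd_m >= 0,
            pixel_noise_sd_px >= 0, missing_rate >= 0, missing_rate < 1)
  structure(list(stride_time_s = stride_time_s,
                 stride_length_m = stride_length_m,
                 duty_factor = duty_factor, step_width_m = step_width_m,
                 thigh_m = thigh_m, shank_m = shank_m, foot_m = foot_m,
                 pelvis_height_m = pelvis_height_m, fps = fps,
                 duration_s = duration_s,
                 trajectory_noise_sd_m = trajectory_noise_sd_m,
                 pixel_noise_sd_px = pixel_noise_sd_px,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "gait_sim_config")
}

# fixed internal magnitudes of the toy walker (chosen once for realism)
sim_const <- list(
  heel_marker_h = 0.03,     # heel keypoint height when foot is flat (m)
  toe_marker_h = 0.02,      # toe keypoint height when foot is flat (m)
  ankle_h = 0.08,           # ankle above heel along the foot normal (m)
  heel_clearance = 0.12,    # peak heel rise during swing (m)
  pelvis_vosc = 0.015,      # vertical pelvis oscillation amplitude (m)
  pelvis_losc = 0.020,      # lateral sway amplitude (m)
  pelvis_tilt0 = 4,         # mean anterior pelvic tilt (deg)
  pelvis_tilt_amp = 1.5,    # tilt oscillation amplitude (deg)
  foot_pitch_amp = 20,      # swing foot pitch amplitude (deg)
  arm_swing_amp = 0.26,     # arm swing amplitude (rad)
  x_start = 0.3)            # pelvis x at t = 0 (m)

min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# first right-heel strike: half a second in, so the first analyzed event is
# clear of the record edge (recordings have lead-in before the first clean
# strike; filters need settled history)
sim_f0 <- function(cfg) as.integer(round(0.5 * cfg$fps))

# continuous-time model: evaluate all 21 keypoints at times t (seconds).
# Returns length(t) x 21 x 3 array in h36m21 order, plus pelvis pitch (rad).
sim_eval <- function(cfg, t) {
  N <- round(cfg$stride_time_s * cfg$fps)
  Tq <- N / cfg$fps                       # quantized stride time
  v <- cfg$stride_length_m / Tq
  L <- cfg$stride_length_m
  d <- cfg$duty_factor
  w2 <- cfg$step_width_m / 2
  f0R <- sim_f0(cfg)                      # first right strike frame (0-based)
  f0L <- f0R + N %/% 2L
  t0R <- f0R / cfg$fps
  t0L <- f0L / cfg$fps
  cs <- sim_const

  nt <- length(t)
  kp <- skeleton_h36m21()$keypoints
  out <- array(NA_real_, c(nt, length(kp), 3), dimnames = list(NULL, kp, NULL))

  # pelvis root and orientation
  px <- cs$x_start + v * t
  py <- cfg$pelvis_height_m - cs$pelvis_vosc * cos(4 * pi * (t - t0R) / Tq)
  pz <- -cs$pelvis_losc * sin(2 * pi * (t - t0R) / Tq)
  pitch <- (cs$pelvis_tilt0 +
            cs$pelvis_tilt_amp * sin(4 * pi * (t - t0R) / Tq)) * pi / 180
  root <- cbind(px, py, pz)
  out[, "pelvis", ] <- root

  # pelvis-frame axes (anterior tilt = forward axis pitched down by `pitch`)
  fwd <- cbind(cos(pitch), -sin(pitch), 0)
  up <- cbind(sin(pitch), cos(pitch), 0)

  # trunk column and head (rigid in the pelvis frame)
  out[, "spine", ] <- root + 0.20 * up
  out[, "neck", ]  <- root + 0.45 * up
  out[, "head", ]  <- root + 0.60 * up
  out[, "nose", ]  <- root + 0.55 * up + 0.10 * fwd

  # legs
  for (side in c("right", "left")) {
    sgn <- if (side == "right") -1 else 1   # heel line at z = sgn * w/2
    ts <- if (side == "right") t0R else t0L
    ph <- (t - ts) / Tq
    k <- floor(ph)
    tau_c <- ph - k                         # phase within cycle [0,1)
    stance <- tau_c < d
    tau_sw <- pmax(0, (tau_c - d) / (1 - d))

    # heel: anchored at x_k during stance; min-jerk advance during swing
    xk <- v * (ts + k * Tq + d * Tq / 2)    # pelvis passes over mid-stance
    xk <- cs$x_start + xk
    hx <- ifelse(stance, xk, xk + L * min_jerk(tau_sw))
    hy <- cs$heel_marker_h +
      ifelse(stance, 0, cs$heel_clearance * sin(pi * tau_sw)^2)
    hz <- rep(sgn * w2, nt)
    heel <- cbind(hx, hy, hz)

    # foot pitch: flat in stance; plantar- then dorsi-flexion in swing.
    # The sin(2*pi*tau)*sin(pi*tau) product vanishes with zero slope at
    # both stance boundaries (C1), as a physiological pitch profile does;
    # the 1.3 factor restores the nominal peak amplitude.
    beta <- ifelse(stance, 0,
                   -cs$foot_pitch_amp * pi / 180 * 1.3 *
                     sin(2 * pi * tau_sw) * sin(pi * tau_sw))
    fl <- cfg$foot_m
    toe <- heel + cbind(fl * cos(beta),
                        fl * sin(beta) + (cs$toe_marker_h - cs$heel_marker_h),
                        0)
    ankle <- heel + cbind(-cs$ankle_h * sin(beta), cs$ankle_h * cos(beta), 0)

    hip <- root
    hip[, 3] <- hip[, 3] + sgn * w2
    dvec <- ankle - hip
    dd <- sqrt(rowSums(dvec^2))
    reach <- cfg$thigh_m + cfg$shank_m
    if (any(dd > reach)) {
      stop("IK infeasible: hip-ankle distance ", round(max(dd), 3),
           " m exceeds thigh + shank = ", reach, " m")
    }
    u <- dvec / dd
    # knee bends forward: in-plane normal = forward component orthogonal to u
    fref <- matrix(rep(c(1, 0, 0), each = nt), nt, 3)
    nvec <- fref - u * rowSums(fref * u)
    nn <- sqrt(rowSums(nvec^2))
    nvec <- nvec / pmax(nn, 1e-12)
    cosa <- (cfg$thigh_m^2 + dd^2 - cfg$shank_m^2) / (2 * cfg$thigh_m * dd)
    cosa <- pmin(1, pmax(-1, cosa))
    sina <- sqrt(1 - cosa^2)
    knee <- hip + cfg$thigh_m * (u * cosa + nvec * sina)

    out[, paste0(side, "_hip"), ] <- hip
    out[, paste0(side, "_knee"), ] <- knee
    out[, paste0(side, "_ankle"), ] <- ankle
    out[, paste0(side, "_heel"), ] <- heel
    out[, paste0(side, "_toe"), ] <- toe
  }

  # arms: simple pendulum swing, antiphase with the ipsilateral leg
  for (side in c("right", "left")) {
    sgn <- if (side == "right") -1 else 1
    ts <- if (side == "right") t0R else t0L
    a <- -sim_const$arm_swing_amp * cos(2 * pi * (t - ts) / Tq + pi)
    sh <- out[, "neck", , drop = FALSE][, 1, ] + 0
    sh <- matrix(sh, nt, 3)
    sh[, 3] <- sh[, 3] + sgn * 0.18
    elbow <- sh + cbind(0.28 * sin(a), -0.28 * cos(a), 0)
    wrist <- elbow + cbind(0.25 * sin(a + 0.3), -0.25 * cos(a + 0.3), 0)
    out[, paste0(side, "_shoulder"), ] <- sh
    out[, paste0(side, "_elbow"), ] <- elbow
    out[, paste0(side, "_wrist"), ] <- wrist
  }
  list(coords = out, pitch = pitch, N = N, Tq = Tq, v = v,
       f0R = f0R, f0L = f0L)
}

#' Simulate a ground-truthed walking trial
#'
#' @param config a [gait_sim_config()].
#' @return List with `series` (a `kps3d`, noise applied per config) and
#'   `truth` (a `gait_ground_truth`: noise-free series, heel-strike and
#'   toe-off frames per side (0-based), per-cycle true spatio-temporal
#'   parameters, and prescribed joint-angle profiles per side at 101 nodes).
#' @export
simulate_walk <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  cfg <- config
  n <- round(cfg$duration_s * cfg$fps)
  t <- (seq_len(n) - 1L) / cfg$fps
  ev <- sim_eval(cfg, t)
  co <- ev$coords
  N <- ev$N

  truth_events <- lapply(c(right = "right", left = "left"), function(side) {
    f0 <- if (side == "right") ev$f0R else ev$f0L
    ks <- 0:floor((n - 1 - f0) / N)
    hs <- f0 + ks * N
    hs <- hs[hs >= 0 & hs <= n - 1]
    to <- hs + round(cfg$duty_factor * N)
    list(heel_strikes = hs, toe_offs = to[to <= n - 1])
  })

  # per-cycle exact parameters (identical for every complete cycle)
  true_params <- do.call(rbind, lapply(names(truth_events), function(side) {
    hs <- truth_events[[side]]$heel_strikes
    ncyc <- max(0L, length(hs) - 1L)
    if (!ncyc) return(NULL)
    data.frame(side = side,
               start_frame = hs[seq_len(ncyc)],
               end_frame = hs[seq_len(ncyc) + 1L],
               stride_length_m = cfg$stride_length_m,
               stride_time_s = N / cfg$fps,
               stance_pct = cfg$duty_factor * 100,
               swing_pct = (1 - cfg$duty_factor) * 100,
               stride_width_m = cfg$step_width_m,
               speed_m_s = cfg$stride_length_m * cfg$fps / N)
  }))

  angles <- lapply(c(right = "right", left = "left"), function(side) {
    sim_true_angles(cfg, side)
  })

  clean <- keypoint_series_3d(co, cfg$fps, vertical_axis = "Y",
                              skeleton = skeleton_h36m21())
  noisy <- clean
  if (cfg$trajectory_noise_sd_m > 0 || cfg$missing_rate > 0) {
    noisy <- with_sim_rng(cfg$seed, {
      co2 <- co
      if (cfg$trajectory_noise_sd_m > 0) {
        co2 <- co2 + array(stats::rnorm(length(co2), 0,
                                        cfg$trajectory_noise_sd_m), dim(co2))
      }
      if (cfg$missing_rate > 0) {
        drop <- matrix(stats::runif(n * dim(co2)[2]) < cfg$missing_rate,
                       n, dim(co2)[2])
        co2[rep(drop, 3)] <- NA_real_
      }
      keypoint_series_3d(co2, cfg$fps, vertical_axis = "Y",
                         skeleton = skeleton_h36m21())
    })
  }

  truth <- structure(list(
    series = clean,
    heel_strike_frames = lapply(truth_events, `[[`, "heel_strikes"),
    toe_off_frames = lapply(truth_events, `[[`, "toe_offs"),
    params = true_params,
    angle_profiles = angles,
    config = cfg), class = "gait_ground_truth")
  list(series = noisy, truth = truth)
}

# closed-form ground-truth joint-angle profiles over one steady-state cycle,
# sampled at 101 nodes of the cycle, using the analytic pelvis frame.
sim_true_angles <- function(cfg, side) {
  N <- round(cfg$stride_time_s * cfg$fps)
  Tq <- N / cfg$fps
  f0 <- sim_f0(cfg) + if (side == "right") 0L else N %/% 2L
  # a mid-record cycle start, away from the record edge
  k <- max(1L, floor((cfg$duration_s / Tq) / 2) - 1L)
  tt <- f0 / cfg$fps + k * Tq + seq(0, 1, length.out = 101L) * Tq
  ev <- sim_eval(cfg, tt)
  co <- ev$coords
  pitch <- ev$pitch
  fwd <- cbind(cos(pitch), -sin(pitch), 0)
  up <- cbind(sin(pitch), cos(pitch), 0)
  lat <- matrix(rep(c(0, 0, 1), each = 101L), 101L, 3)  # pointing left
  down <- -up
  sgn_out <- if (side == "right") -1 else 1

  hip <- co[, paste0(side, "_hip"), ]
  knee <- co[, paste0(side, "_knee"), ]
  ankle <- co[, paste0(side, "_ankle"), ]
  heel <- co[, paste0(side, "_heel"), ]
  toe <- co[, paste0(side, "_toe"), ]

  thigh <- knee - hip
  shank <- ankle - knee
  foot <- toe - heel

  hipf <- atan2(rowSums(thigh * fwd), rowSums(thigh * down)) * 180 / pi
  kneef <- 180 - angle_between_rows(-thigh, shank)
  hipa <- atan2(sgn_out * rowSums(thigh * lat), rowSums(thigh * down)) *
    180 / pi
  tilt <- pitch * 180 / pi
  # ankle: signed sagittal angle foot-vs-shank, minus its mid-stance value
  raw <- sagittal_signed_angle(foot, shank, fwd, up)
  mid <- sagittal_signed_angle_at_midstance(cfg, side)
  ankf <- raw - mid
  list(hip_flexion = hipf, knee_flexion = kneef,
       ankle_dorsiflexion = ankf, hip_abduction = hipa,
       pelvis_tilt = rep(tilt, length.out = 101L))
}

sagittal_signed_angle_at_midstance <- function(cfg, side) {
  N <- round(cfg$stride_time_s * cfg$fps)
  Tq <- N / cfg$fps
  f0 <- sim_f0(cfg) + if (side == "right") 0L else N %/% 2L
  # neutral frame convention matches the analysis side: strike plus half
  # the (frame-quantized) stance duration, on the frame grid
  tm <- (f0 + N + round(round(cfg$duty_factor * N) / 2)) / cfg$fps
  ev <- sim_eval(cfg, tm)
  co <- ev$coords
  pitch <- ev$pitch
  fwd <- cbind(cos(pitch), -sin(pitch), 0)
  up <- cbind(sin(pitch), cos(pitch), 0)
  foot <- co[, paste0(side, "_toe"), , drop = FALSE] -
    co[, paste0(side, "_heel"), , drop = FALSE]
  shank <- co[, paste0(side, "_ankle"), , drop = FALSE] -
    co[, paste0(side, "_knee"), , drop = FALSE]
  sagittal_signed_angle(matrix(foot, 1, 3), matrix(shank, 1, 3),
                        matrix(fwd, 1, 3), matrix(up, 1, 3))
}

# signed angle (deg) from the shank to the foot vector in the sagittal
# plane spanned by (forward, up); dorsiflexion (toe pulled up) positive
sagittal_signed_angle <- function(foot, shank, fwd, up) {
  fx <- rowSums(foot * fwd); fy <- rowSums(foot * up)
  sx <- rowSums(shank * fwd); sy <- rowSums(shank * up)
  a <- atan2(fy, fx) - atan2(sy, sx)
  a <- (a + pi) %% (2 * pi) - pi
  a * 180 / pi
}

angle_between_rows <- function(a, b) {
  ca <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# run expr with a private RNG stream; leaves the global stream untouched
with_sim_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default virtual camera rig (three cameras along a 6 m walkway)
#'
#' Mimics a typical laboratory multi-view setup: three RGB cameras on one
#' side of a 6 m walkway at ~3.5-4.5 m distance, 1292 x 964 px.
#'
#' @param f_px focal length in pixels (default 900).
#' @param image_size pixel dimensions.
#' @param dist distortion coefficients applied to every camera.
#' @return Named list of three [camera_model()] objects.
#' @export
default_camera_rig <- function(f_px = 900, image_size = c(1292, 964),
                               dist = c(0, 0, 0, 0)) {
  target <- c(3, 0.9, 0)
  pos <- list(cam1 = c(3, 1.2, 4.5),
              cam2 = c(-1.5, 1.5, 3.5),
              cam3 = c(7.5, 1.5, 3.5))
  K <- intrinsic_matrix(f_px, f_px, image_size[1] / 2, image_size[2] / 2)
  cams <- lapply(names(pos), function(id) {
    R <- look_at_rotation(pos[[id]], target)
    camera_model(id, K = K, R = R, t = -R %*% pos[[id]], dist = dist,
                 image_size = image_size)
  })
  stats::setNames(cams, names(pos))
}

look_at_rotation <- function(position, target, up = c(0, 1, 0)) {
  z <- target - position
  z <- z / sqrt(sum(z^2))
  x <- c(up[2] * z[3] - up[3] * z[2],
         up[3] * z[1] - up[1] * z[3],
         up[1] * z[2] - up[2] * z[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rbind(x, y, z)
}

#' Render a 3D series into per-view 2D detections
#'
#' Projects every sample through each camera, adds isotropic Gaussian pixel
#' noise, and drops samples at `missing_rate` (dropped samples get
#' confidence 0). Keypoints behind a camera are marked missing for that
#' view, never fatal. Deterministic given `seed`.
#'
#' @param series a `kps3d`.
#' @param cameras named list of `camera_model`.
#' @param pixel_noise_sd_px Gaussian pixel noise SD.
#' @param missing_rate per-sample drop probability in [0, 1).
#' @param seed integer seed.
#' @return List of `kps2d`, one per camera.
#' @export
render_views <- function(series, cameras, pixel_noise_sd_px = 0,
                         missing_rate = 0, seed = 1L) {
  stopifnot(inherits(series, "kps3d"))
  n <- series$frames
  K <- length(series$keypoints)
  with_sim_rng(seed, {
    lapply(cameras, function(cam) {
      uv <- array(NA_real_, c(n, K, 2))
      conf <- matrix(0, n, K)
      for (k in seq_len(K)) {
        pts <- series$coords[, k, , drop = TRUE]
        if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
        ok <- !series$missing[, k]
        if (any(ok)) {
          Xc <- pts[ok, , drop = FALSE] %*% t(cam$R) +
            rep(cam$t, each = sum(ok))
          front <- Xc[, 3] > 0
          idx <- which(ok)[front]
          if (length(idx)) {
            uv[idx, k, ] <- project_point(cam, pts[idx, , drop = FALSE])
            conf[idx, k] <- 1
          }
        }
      }
      if (pixel_noise_sd_px > 0) {
        uv <- uv + array(stats::rnorm(length(uv), 0, pixel_noise_sd_px),
                         dim(uv))
      }
      if (missing_rate > 0) {
        drop <- matrix(stats::runif(n * K) < missing_rate, n, K)
        uv[rep(drop, 2)] <- NA_real_
        conf[drop] <- 0
      }
      keypoint_series_2d(uv, series$fps, camera_id = cam$camera_id,
                         keypoints = series$keypoints, confidence = conf,
                         skeleton = series$skeleton)
    })
  })
}
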