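# shared fixtures: small camera rigs, random series, smooth null fields

test_rig <- function(f_px = 900, dist = c(0, 0, 0, 0)) {
  default_camera_rig(f_px = f_px, dist = dist)
}

random_camera <- function(id = "rc", dist = c(0, 0, 0, 0)) {
  # random rotation via QR of a Gaussian matrix, det +1
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  pos <- c(runif(1, -2, 8), runif(1, 0.5, 2.5), runif(1, 3, 6))
  # look roughly at the walkway center so test points stay in front
  R <- gaitless:::look_at_rotation(pos, c(3, 0.9, 0) + rnorm(3, 0, 0.2))
  camera_model(id, intrinsic_matrix(900, 900, 646, 482), R = R,
               t = -R %*% pos, dist = dist)
}

walkway_point <- function(n = 1) {
  cbind(runif(n, 0.5, 5.5), runif(n, 0.1, 1.8), runif(n, -0.5, 0.5))
}

random_series_3d <- function(frames = 20, keypoints = c("a", "b", "c"),
                             fps = 30) {
  co <- array(rnorm(frames * length(keypoints) * 3), c(frames,
              length(keypoints), 3))
  keypoint_series_3d(co, fps, keypoints = keypoints)
}

# Gaussian-smoothed unit-variance 1D null fields (subjects x nodes)
smooth_null_curves <- function(n, nodes = 101, fwhm = 20) {
  sdk <- fwhm / sqrt(8 * log(2))
  pad <- ceiling(3 * sdk)
  kern <- stats::dnorm(seq(-pad, pad), 0, sdk)
  kern <- kern / sqrt(sum(kern^2))   # unit output variance for white input
  t(vapply(seq_len(n), function(i) {
    w <- stats::rnorm(nodes + 2 * pad)
    stats::convolve(w, kern, type = "filter")
  }, numeric(nodes)))
}

sim_quick <- function(..., seed = 1) {
  simulate_walk(gait_sim_config(..., seed = seed))
}

# build a rigid walking pose with prescribed knee geometry: the whole body
# translates along +X so the progression axis is defined, while the leg
# shape (and hence every joint angle) stays constant over time
rigid_pose_series <- function(knee_angle_deg, frames = 40, fps = 30) {
  sk <- skeleton_h36m21()
  kp <- sk$keypoints
  co <- array(NA_real_, c(frames, length(kp), 3),
              dimnames = list(NULL, kp, NULL))
  base <- list(
    pelvis = c(0, 1.0, 0), spine = c(0, 1.2, 0), neck = c(0, 1.45, 0),
    head = c(0, 1.6, 0), nose = c(0.1, 1.55, 0),
    left_shoulder = c(0, 1.45, 0.18), right_shoulder = c(0, 1.45, -0.18),
    left_elbow = c(0, 1.17, 0.18), right_elbow = c(0, 1.17, -0.18),
    left_wrist = c(0, 0.92, 0.18), right_wrist = c(0, 0.92, -0.18),
    left_hip = c(0, 1.0, 0.1), right_hip = c(0, 1.0, -0.1))
  # left leg: straight down. right leg: knee bent by knee_angle_deg in the
  # sagittal plane (shank rotated forward about the knee)
  th <- 0.45; sh <- 0.45
  base$left_knee <- base$left_hip + c(0, -th, 0)
  base$left_ankle <- base$left_knee + c(0, -sh, 0)
  base$left_heel <- base$left_ankle + c(-0.05, -0.05, 0)
  base$left_toe <- base$left_heel + c(0.2, -0.01, 0)
  a <- knee_angle_deg * pi / 180
  base$right_knee <- base$right_hip + c(0, -th, 0)
  base$right_ankle <- base$right_knee + sh * c(sin(a), -cos(a), 0)
  base$right_heel <- base$right_ankle + c(-0.05, -0.05, 0)
  base$right_toe <- base$right_heel + c(0.2, -0.01, 0)
  for (f in seq_len(frames)) {
    for (nm in kp) co[f, nm, ] <- base[[nm]] + c(0.04 * (f - 1), 0, 0)
  }
  keypoint_series_3d(co, fps, skeleton = sk)
}

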