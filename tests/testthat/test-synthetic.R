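test_that("config invariants are enforced and seed is required", {
  expect_error(gait_sim_config(), "seed")
  expect_error(gait_sim_config(duty_factor = 0.3, seed = 1), "duty_factor")
  expect_error(gait_sim_config(stride_length_m = 2.5, seed = 1),
               "stride_length")
  expect_error(gait_sim_config(fps = 5, seed = 1), "fps")
})

test_that("ground truth is an exact function of the config", {
  cfg <- gait_sim_config(stride_time_s = 1.13, duty_factor = 0.592,
                         duration_s = 6, seed = 1)
  sim <- simulate_walk(cfg)
  tr <- sim$truth
  expect_equal(tr$params$stance_pct[1], 59.2)
  N <- round(1.13 * 30)
  expect_true(all(diff(tr$heel_strike_frames$right) == N))
  expect_true(all(diff(tr$heel_strike_frames$left) == N))
  expect_equal(tr$params$stride_time_s[1], N / 30)
  expect_equal(tr$params$speed_m_s[1], 1.35 * 30 / N)

  # heel speed during ground-truth stance is exactly zero
  heel <- kp_traj(tr$series, "right_heel")
  for (k in seq_len(length(tr$heel_strike_frames$right) - 1L)) {
    hs <- tr$heel_strike_frames$right[k]
    to <- tr$toe_off_frames$right[k]
    span <- (hs + 1):(to)          # 1-based stance frames (minus boundary)
    expect_equal(max(abs(diff(heel[span, 1]))), 0)
    expect_equal(max(abs(diff(heel[span, 2]))), 0)
  }
})

test_that("two-link inverse kinematics keeps segment lengths exact", {
  cfg <- gait_sim_config(duration_s = 4, seed = 2)
  sim <- simulate_walk(cfg)
  s <- sim$truth$series
  for (side in c("left", "right")) {
    hip <- kp_traj(s, paste0(side, "_hip"))
    knee <- kp_traj(s, paste0(side, "_knee"))
    ankle <- kp_traj(s, paste0(side, "_ankle"))
    expect_lt(max(abs(sqrt(rowSums((hip - knee)^2)) - cfg$thigh_m)), 1e-9)
    expect_lt(max(abs(sqrt(rowSums((knee - ankle)^2)) - cfg$shank_m)), 1e-9)
  }
})

test_that("infeasible leg geometry raises an IK error", {
  cfg <- gait_sim_config(thigh_m = 0.35, shank_m = 0.35,
                         stride_length_m = 1.35, pelvis_height_m = 0.88,
                         seed = 1)
  expect_error(simulate_walk(cfg), "IK infeasible")
})

test_that("the simulator is deterministic given its seed", {
  cfg <- gait_sim_config(trajectory_noise_sd_m = 0.002, missing_rate = 0.03,
                         duration_s = 3, seed = 99)
  a <- simulate_walk(cfg)
  b <- simulate_walk(cfg)
  expect_identical(a$series$coords, b$series$coords)
  expect_identical(a$series$missing, b$series$missing)

  cams <- test_rig()
  va <- render_views(a$truth$series, cams, pixel_noise_sd_px = 0.7,
                     missing_rate = 0.05, seed = 5)
  vb <- render_views(a$truth$series, cams, pixel_noise_sd_px = 0.7,
                     missing_rate = 0.05, seed = 5)
  for (i in seq_along(va)) {
    expect_identical(va[[i]]$coords, vb[[i]]$coords)
    expect_identical(va[[i]]$confidence, vb[[i]]$confidence)
  }
})

test_that("render/triangulate round-trip is exact without noise", {
  sim <- sim_quick(duration_s = 2, seed = 3)
  cams <- test_rig()
  views <- render_views(sim$truth$series, cams, seed = 1)
  tri <- triangulate_series(views, cams)
  expect_lt(max(abs(tri$coords - sim$truth$series$coords)), 1e-6)

  # dropping one whole view still reconstructs from the other two
  tri2 <- triangulate_series(views[1:2], cams)
  expect_false(any(tri2$missing))
  expect_lt(max(abs(tri2$coords - sim$truth$series$coords)), 1e-5)
})

test_that("behind-camera keypoints are marked missing, not fatal", {
  co <- array(rep(c(3, 1, 10), each = 5), c(5, 1, 3))  # behind cam1 (z=4.5)
  co[3, 1, ] <- c(3, 1, 0)                             # one visible frame
  s <- keypoint_series_3d(co, 30, keypoints = "pelvis",
                          skeleton = skeleton_h36m21())
  v <- render_views(s, test_rig()["cam1"], seed = 1)[[1]]
  expect_true(all(v$missing[-3, 1]))
  expect_false(v$missing[3, 1])
})

test_that("noise and missingness are applied after truth is recorded", {
  cfg <- gait_sim_config(trajectory_noise_sd_m = 0.004, missing_rate = 0.02,
                         duration_s = 3, seed = 7)
  sim <- simulate_walk(cfg)
  expect_false(any(sim$truth$series$missing))
  expect_gt(sum(sim$series$missing), 0)
  ok <- !sim$series$missing
  dev <- abs(sim$series$coords - sim$truth$series$coords)
  dev <- dev[!is.na(dev)]
  expect_gt(stats::sd(dev), 0)
  expect_lt(max(dev), 0.004 * 6)
})
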