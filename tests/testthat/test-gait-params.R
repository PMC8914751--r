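test_that("walking_direction finds the progression axis", {
  sim <- sim_quick(duration_s = 5, seed = 1)
  dir <- walking_direction(sim$series)
  expect_equal(dir$progression, c(1, 0, 0), tolerance = 1e-6)
  expect_equal(sum(dir$progression * dir$lateral), 0, tolerance = 1e-12)
  expect_equal(dir$vertical, c(0, 1, 0))

  # standing record
  co <- array(rep(c(1, 0.9, 0), each = 60), c(60, 1, 3))
  s <- keypoint_series_3d(co, 30, keypoints = "pelvis",
                          skeleton = skeleton_h36m21())
  expect_error(walking_direction(s), "no progression")
})

test_that("parameters recover the simulator ground truth", {
  sim <- sim_quick(duration_s = 6, seed = 2)
  truth <- sim$truth$params[1, ]
  pp <- compute_params_all(sim$series)
  expect_gte(nrow(pp), 6L)
  expect_equal(max(abs(pp$stride_length_m - truth$stride_length_m)), 0,
               tolerance = 0.01)
  expect_equal(max(abs(pp$stride_time_s - truth$stride_time_s)), 0,
               tolerance = 1 / 30 + 1e-9)
  expect_lte(max(abs(pp$stance_pct - truth$stance_pct)), 1)
  expect_equal(max(abs(pp$stride_width_m - truth$stride_width_m)), 0,
               tolerance = 0.005)
  expect_lte(max(abs(pp$speed_m_s - truth$speed_m_s)), 0.02)
  expect_equal(pp$stance_pct + pp$swing_pct, rep(100, nrow(pp)))
})

test_that("parameters are invariant to vertical-axis rigid motions", {
  sim <- sim_quick(duration_s = 6, seed = 3)
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- transform_series(sim$series, R, c(5, 0.2, -3))
  p0 <- compute_params_all(sim$series)
  p1 <- compute_params_all(moved)
  expect_equal(nrow(p0), nrow(p1))
  for (cc in c("stride_length_m", "stride_time_s", "stance_pct",
               "stride_width_m", "speed_m_s")) {
    expect_equal(p1[[cc]], p0[[cc]], tolerance = 1e-7)
  }
})

test_that("lengths scale and times do not under uniform scaling", {
  sim <- sim_quick(duration_s = 5, seed = 4)
  scaled <- sim$series
  scaled$coords <- scaled$coords * 2
  p0 <- compute_params_all(sim$series)
  p1 <- compute_params_all(scaled)
  n <- min(nrow(p0), nrow(p1))
  expect_equal(p1$stride_length_m[1:n], 2 * p0$stride_length_m[1:n],
               tolerance = 1e-6)
  expect_equal(p1$stride_width_m[1:n], 2 * p0$stride_width_m[1:n],
               tolerance = 1e-6)
  expect_equal(p1$stride_time_s[1:n], p0$stride_time_s[1:n])
  expect_equal(p1$stance_pct[1:n], p0$stance_pct[1:n])
})

test_that("time reversal preserves stride length and speed", {
  sim <- sim_quick(duration_s = 6, seed = 5)
  rev_co <- sim$series$coords[sim$series$frames:1, , , drop = FALSE]
  revs <- keypoint_series_3d(rev_co, sim$series$fps,
                             skeleton = sim$series$skeleton)
  p0 <- compute_params_all(sim$series)
  p1 <- compute_params_all(revs)
  expect_gt(nrow(p1), 0L)
  expect_equal(mean(p1$stride_length_m), mean(p0$stride_length_m),
               tolerance = 0.01)
  expect_equal(mean(p1$speed_m_s), mean(p0$speed_m_s), tolerance = 0.02)
})

test_that("speed is consistent with stride_length / stride_time", {
  sim <- sim_quick(duration_s = 6, seed = 6)
  pp <- compute_params_all(sim$series)
  ratio <- pp$speed_m_s / (pp$stride_length_m / pp$stride_time_s)
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("stride width is absent when the contralateral heel is missing", {
  sim <- sim_quick(duration_s = 5, seed = 7)
  s <- sim$series
  cycles <- segment_cycles(s)
  cy <- Find(function(c) c$side == "right", cycles)
  s$missing[, "left_heel"] <- TRUE
  s$coords[, "left_heel", ] <- NA
  # left heel gone entirely: width NA, other parameters still computed.
  # prepare by hand because interpolate_gaps would reject the empty keypoint
  keep <- setdiff(s$keypoints, "left_heel")
  sk <- skeleton_h36m21()
  sk$roles$left_heel <- NULL
  sk$keypoints <- setdiff(sk$keypoints, "left_heel")
  sk$bones <- NULL
  s2 <- keypoint_series_3d(sim$series$coords[, keep, , drop = FALSE],
                           s$fps, skeleton = sk)
  p <- compute_params(s2, cy)
  expect_true(is.na(p$stride_width_m))
  expect_false(is.na(p$stride_length_m))
  expect_false(is.na(p$speed_m_s))
})

test_that("summary tables are exact aggregates of per-cycle values", {
  set.seed(8)
  params <- do.call(rbind, lapply(1:4, function(subj) {
    sim <- sim_quick(duration_s = 5, seed = subj,
                     trajectory_noise_sd_m = 0.001)
    p <- compute_params_all(sim$series)
    p$subject <- paste0("s", subj)
    p
  }))
  sm <- summarize_params(params, by = "subject")
  for (g in sm$subject) {
    idx <- params$subject == g
    expect_equal(sm$stride_length_m_mean[sm$subject == g],
                 mean(params$stride_length_m[idx]))
    expect_equal(sm$stance_pct_sd[sm$subject == g],
                 sd(params$stance_pct[idx]))
  }
  overall <- summarize_params(params)
  expect_equal(overall$speed_m_s_mean, mean(params$speed_m_s))
})
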