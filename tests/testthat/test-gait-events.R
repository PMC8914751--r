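test_that("events match simulator ground truth across the gait grid", {
  for (st in c(0.9, 1.1, 1.3)) {
    for (duty in c(0.55, 0.60, 0.65)) {
      sim <- sim_quick(stride_time_s = st, duty_factor = duty,
                       duration_s = 6, seed = 1)
      for (side in c("left", "right")) {
        hs <- detect_heel_strikes(sim$series, side)
        to <- detect_toe_off(sim$series, side, hs)
        ghs <- sim$truth$heel_strike_frames[[side]]
        gto <- sim$truth$toe_off_frames[[side]]
        expect_equal(length(hs), length(ghs))
        expect_lte(max(abs(hs - ghs)), 1L)
        expect_lte(max(vapply(to, function(x) min(abs(x - gto)),
                              numeric(1))), 1L)
      }
    }
  }
})

test_that("noisy trajectories still yield every cycle within 2 frames", {
  for (seed in 1:20) {
    sim <- sim_quick(trajectory_noise_sd_m = 0.003, duration_s = 6,
                     seed = seed)
    for (side in c("left", "right")) {
      hs <- detect_heel_strikes(sim$series, side)
      ghs <- sim$truth$heel_strike_frames[[side]]
      expect_equal(length(hs), length(ghs))   # none missed, none spurious
      expect_lte(max(abs(hs - ghs)), 2L)
    }
  }
})

test_that("degenerate records return empty results with diagnostics", {
  co <- array(rep(c(1, 0.03, 0.05), each = 90), c(90, 1, 3))
  s <- keypoint_series_3d(co, 30, keypoints = "left_heel",
                          skeleton = skeleton_h36m21())
  hs <- detect_heel_strikes(s, "left")
  expect_length(hs, 0L)
  expect_match(attr(hs, "diagnostic"), "no gait")

  expect_error(detect_heel_strikes(crop_series(s, 1, 20), "left"),
               "1 s")

  sim <- sim_quick(duration_s = 4, seed = 2)
  expect_length(detect_toe_off(sim$series, "left", heel_strikes = 32L), 0L)
})

test_that("toe-off falls back to the heel when no toe keypoint exists", {
  sim <- sim_quick(duration_s = 5, seed = 2)
  s <- sim$series
  keep <- setdiff(s$keypoints, c("left_toe", "right_toe"))
  sk <- skeleton_h36m21()
  sk$roles$left_toe <- NULL
  sk$roles$right_toe <- NULL
  sk$keypoints <- setdiff(sk$keypoints, c("left_toe", "right_toe"))
  sk$bones <- NULL
  s2 <- keypoint_series_3d(s$coords[, keep, , drop = FALSE], s$fps,
                           skeleton = sk)
  hs <- detect_heel_strikes(s2, "right")
  to <- detect_toe_off(s2, "right", hs)
  expect_true(attr(to, "used_fallback"))
  expect_length(to, length(hs) - 1L)
  # heel-off equals toe-off in the simulator, so accuracy is preserved
  gto <- sim$truth$toe_off_frames$right
  expect_lte(max(vapply(to, function(x) min(abs(x - gto)), numeric(1))), 1L)
})

test_that("event detection is equivariant to frame shifts", {
  sim <- sim_quick(duration_s = 6, seed = 3)
  k <- 7L
  shifted <- crop_series(sim$series, k + 1L, sim$series$frames)
  hs0 <- detect_heel_strikes(sim$series, "right")
  hs1 <- detect_heel_strikes(shifted, "right")
  # events away from the cropped edge shift by exactly k
  common <- intersect(hs0 - k, hs1)
  expect_gte(length(common), length(hs0) - 1L)
})

test_that("segment_cycles builds valid alternating cycles", {
  for (seed in 1:10) {
    sim <- sim_quick(duration_s = 6, seed = seed,
                     trajectory_noise_sd_m = 0.001)
    cycles <- segment_cycles(sim$series)
    expect_gte(length(cycles), 4L)
    for (cy in cycles) {
      expect_lt(cy$start_frame, cy$toe_off_frame)
      expect_lt(cy$toe_off_frame, cy$end_frame)
      expect_equal(cy$stance_fraction + cy$swing_fraction, 1)
    }
    for (side in c("left", "right")) {
      expect_equal(sum(vapply(cycles, function(c) {
        c$side == side && c$central
      }, logical(1))), 1L)
    }
    # alternation: each left start lies between consecutive right starts
    rs <- sort(vapply(Filter(function(c) c$side == "right", cycles),
                      `[[`, integer(1), "start_frame"))
    ls <- sort(vapply(Filter(function(c) c$side == "left", cycles),
                      `[[`, integer(1), "start_frame"))
    for (l in ls) {
      lo <- max(rs[rs < l], -Inf)
      hi <- min(rs[rs > l], Inf)
      expect_true(is.infinite(lo) || is.infinite(hi) || (hi - lo) >= 2)
    }
  }
})

test_that("a 6 m walk yields 3-4 complete cycles per side, central flagged", {
  # 6 m at ~1.19 m/s: ~5 s of steady walking
  sim <- sim_quick(duration_s = 6 / 1.19 + 0.5, seed = 4)
  cycles <- segment_cycles(sim$series)
  for (side in c("left", "right")) {
    n <- sum(vapply(cycles, function(c) c$side == side, logical(1)))
    expect_gte(n, 3L)
    expect_lte(n, 4L)
  }
})

test_that("events_table exports the schema", {
  sim <- sim_quick(duration_s = 5, seed = 5)
  cycles <- segment_cycles(sim$series)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- events_table(cycles, sim$series$fps, f)
  expect_named(df, c("side", "event_type", "frame", "time_s"))
  expect_true(all(df$event_type %in% c("heel_strike", "toe_off")))
  expect_equal(df$time_s, df$frame / 30)
  expect_true(file.exists(f))
})
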