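test_that("2D keypoint CSV round-trips bit-exactly", {
  set.seed(10)
  co <- array(runif(12 * 3 * 2, 0, 1000), c(12, 3, 2))
  cf <- matrix(runif(36), 12, 3)
  s <- keypoint_series_2d(co, fps = 30, camera_id = "camA",
                          keypoints = c("k1", "k2", "k3"), confidence = cf)
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_2d(s, f)
  r <- read_keypoints_2d(f)
  expect_identical(r$coords, s$coords)
  expect_identical(r$confidence, s$confidence)
  expect_identical(r$fps, s$fps)
  expect_identical(r$camera_id, "camA")
})

test_that("missing metadata and sparse rows are handled per contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# camera_id=c0", "frame,keypoint,u,v,confidence",
               "0,a,1,2,0.9"), f)
  expect_error(read_keypoints_2d(f), "fps")

  writeLines(c("# fps=30", "# camera_id=c0", "# frames=2",
               "frame,keypoint,u,v,confidence",
               "0,a,1,2,0.9", "0,b,3,4,0.8", "0,c,5,6,0.7",
               "1,a,1,2,0.9"), f)
  r <- read_keypoints_2d(f)
  expect_false(r$missing[1, "a"])
  expect_true(r$missing[2, "b"])     # sparse: absent rows are missing
  expect_true(r$missing[2, "c"])

  writeLines(c("# fps=30", "# camera_id=c0",
               "frame,keypoint,u,v,confidence",
               "3,a,1,2,0.9", "1,a,3,4,0.8"), f)
  expect_error(read_keypoints_2d(f), "non-monotone")
})

test_that("3D CSV round-trips and converts mm to m", {
  set.seed(11)
  s <- random_series_3d(8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_3d(s, f)
  r <- read_keypoints_3d(f)
  expect_identical(r$coords, s$coords)
  expect_identical(r$vertical_axis, "Y")

  writeLines(c("# fps=30", "# units=mm", "frame,keypoint,x,y,z",
               "0,a,1000,2000,3000"), f)
  expect_message(r2 <- read_keypoints_3d(f), "mm to m")
  expect_equal(drop(r2$coords[1, 1, ]), c(x = 1, y = 2, z = 3))
})

test_that("unknown keypoints against a skeleton are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fps=30", "frame,keypoint,x,y,z", "0,bogus,1,2,3"), f)
  expect_error(read_keypoints_3d(f, skeleton = "h36m21"), "bogus")
})

test_that("declared vertical axis Z is analyzed identically to Y-up", {
  sim <- sim_quick(duration_s = 4, seed = 6)
  s <- sim$series
  # re-express in Z-up axes: (x, y, z) -> (x', y', z') with old Y on new Z
  co <- s$coords[, , c(3, 1, 2), drop = FALSE]   # inverse cyclic permutation
  sz <- keypoint_series_3d(co, s$fps, keypoints = s$keypoints,
                           vertical_axis = "Z", skeleton = s$skeleton)
  back <- canonicalize_axes(sz)
  expect_equal(back$coords, s$coords, tolerance = 1e-12)
  hs_y <- detect_heel_strikes(s, "right")
  hs_z <- detect_heel_strikes(back, "right")
  expect_identical(hs_y, hs_z)
})

test_that("TRC export honors the format contract and parses back", {
  co <- array(c(1.1, 2.2, 0.5, 0.6, 0.7, 0.8,
                0.1, 0.2, 1.5, 1.6, 0.3, 0.4), c(2, 2, 3))
  s <- keypoint_series_3d(co, fps = 30, keypoints = c("m1", "m2"))
  f <- withr::local_tempfile(fileext = ".trc")
  write_trc(s, f)
  lines <- readLines(f)
  expect_match(lines[1], "^PathFileType\t4")
  hdr <- strsplit(lines[3], "\t")[[1]]
  expect_equal(as.integer(hdr[3]), 2L)   # NumFrames
  expect_equal(as.integer(hdr[4]), 2L)   # NumMarkers
  expect_equal(hdr[5], "m")
  # time column: 0 and 1/fps
  rows <- strsplit(lines[7:8], "\t")
  expect_equal(as.numeric(vapply(rows, `[`, "", 2)), c(0, 1 / 30),
               tolerance = 1e-6)
  # independent parse-back of the coordinate block
  vals <- t(vapply(rows, function(r) as.numeric(r[-(1:2)]), numeric(6)))
  expect_equal(vals[1, 1:3], drop(co[1, 1, ]), tolerance = 1e-6)
  expect_equal(vals[2, 4:6], drop(co[2, 2, ]), tolerance = 1e-6)

  s$missing[1, 1] <- TRUE
  s$coords[1, 1, ] <- NA
  expect_error(write_trc(s, f), "missing")
})

test_that("calibration files round-trip bit-exactly and honor units", {
  cams <- test_rig(dist = c(-0.1, 0.02, 1e-3, -2e-4))
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cams, f)
  r <- read_calibration(f)
  expect_identical(names(r), names(cams))
  for (id in names(cams)) {
    expect_identical(r[[id]]$K, cams[[id]]$K)
    expect_identical(r[[id]]$R, cams[[id]]$R)
    expect_identical(r[[id]]$t, cams[[id]]$t)
    expect_identical(r[[id]]$dist, cams[[id]]$dist)
  }
  # mm translations are converted on read
  js <- jsonlite::read_json(f, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  js$units <- "mm"
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(js, f2, auto_unbox = TRUE, digits = NA)
  r2 <- read_calibration(f2)
  expect_equal(r2$cam1$t, cams$cam1$t / 1000)
})

test_that("skeleton definitions enforce their invariants", {
  expect_error(skeleton_definition("s", c("a", "a"), c("left", "left")),
               "duplicated")
  expect_error(skeleton_definition("s", c("a", "b"), c("left", "right"),
                                   bones = rbind(c("a", "zz"))), "zz")
  expect_error(skeleton_definition("s", c("a", "b"), c("left", "right"),
                                   roles = list(left_heel = "nope")),
               "left_heel")
  sk <- skeleton_h36m21()
  expect_length(sk$keypoints, 21L)
  expect_identical(role_keypoint(sk, "pelvis_root"), "pelvis")
  expect_error(role_keypoint(skeleton_davis22(), "left_heel"), "left_heel")
  expect_length(skeleton_davis22()$keypoints, 22L)
})
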