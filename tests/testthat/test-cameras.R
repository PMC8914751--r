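test_that("projection follows the pinhole model", {
  cam <- camera_model("c", intrinsic_matrix(100, 100, 50, 50), diag(3),
                      c(0, 0, 0), image_size = c(100, 100))
  expect_equal(project_point(cam, c(0, 0, 2)), c(u = 50, v = 50))
  expect_equal(project_point(cam, c(1, 0, 2)), c(u = 100, v = 50))
  expect_error(project_point(cam, c(0, 0, -1)), "behind camera")
  expect_error(project_point(cam, c(0, 0, 0)), "behind camera")
})

test_that("camera_model validates its invariants", {
  K <- intrinsic_matrix(100, 100, 50, 50)
  expect_error(camera_model("c", intrinsic_matrix(-1, 100, 50, 50),
                            diag(3), c(0, 0, 0)), "focal")
  expect_error(camera_model("c", K, diag(3) * 1.01, c(0, 0, 0)),
               "orthonormal")
  R_reflect <- diag(c(1, 1, -1))
  expect_error(camera_model("c", K, R_reflect, c(0, 0, 0)), "orthonormal")
  expect_error(camera_model("c", intrinsic_matrix(100, 100, 500, 50),
                            diag(3), c(0, 0, 0),
                            image_size = c(100, 100)), "principal point")
})

test_that("undistortion inverts distortion and rays pass through the point", {
  set.seed(42)
  for (i in 1:20) {
    cam <- random_camera(dist = c(-0.12, 0.03, 1e-3, -5e-4))
    X <- drop(walkway_point())
    uv <- project_point(cam, X)
    xyn <- pixel_to_normalized(cam, uv)
    # ray through the camera center along the undistorted direction
    center <- -t(cam$R) %*% cam$t
    dir <- t(cam$R) %*% c(xyn, 1)
    dir <- dir / sqrt(sum(dir^2))
    v <- X - drop(center)
    dist_to_ray <- sqrt(sum((v - drop(dir) * sum(v * dir))^2))
    expect_lt(dist_to_ray, 1e-9)
  }
})

test_that("reprojection error matches its definition", {
  cam <- camera_model("c", intrinsic_matrix(100, 100, 50, 50), diag(3),
                      c(0, 0, 0), image_size = c(100, 100))
  p <- c(0.2, -0.1, 3)
  uv <- project_point(cam, p)
  expect_equal(reprojection_error(cam, p, uv), 0)
  expect_equal(reprojection_error(cam, p, uv + c(3, 4)), 5)
  set.seed(7)
  for (i in 1:10) {
    cam2 <- random_camera()
    X <- drop(walkway_point())
    obs <- project_point(cam2, X) + rnorm(2)
    expect_equal(reprojection_error(cam2, X, obs),
                 sqrt(sum((project_point(cam2, X) - obs)^2)))
  }
})

test_that("noise-free triangulation recovers the point exactly", {
  cams <- test_rig()
  set.seed(1)
  for (i in 1:20) {
    X <- drop(walkway_point())
    obs <- lapply(cams, function(c) observation_2d(c$camera_id,
                                                   project_point(c, X)))
    tr <- triangulate_point(obs, cams)
    expect_lt(sqrt(sum((tr$point - X)^2)), 1e-9)
    expect_lt(tr$rms_reprojection_error, 1e-7)
    expect_true(tr$reliable)
  }
})

test_that("refinement beats or matches the linear DLT under pixel noise", {
  cams <- test_rig()
  set.seed(2)
  wins <- 0L
  for (i in 1:100) {
    X <- drop(walkway_point())
    obs <- lapply(cams, function(c) {
      observation_2d(c$camera_id, project_point(c, X) + rnorm(2, 0, 0.5))
    })
    dlt <- triangulate_point(obs, cams, refine = FALSE)
    ref <- triangulate_point(obs, cams, refine = TRUE)
    if (ref$rms_reprojection_error <= dlt$rms_reprojection_error + 1e-12) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 95L)
})

test_that("degenerate geometry is rejected or flagged", {
  cams <- test_rig()
  X <- c(3, 1, 0)
  uv <- project_point(cams[[1]], X)
  # one camera only
  expect_error(triangulate_point(list(observation_2d("cam1", uv),
                                      observation_2d("cam1", uv + 1)),
                                 cams), "insufficient views")
  # two cameras with identical pose: no parallax
  twin <- cams[[1]]
  twin$camera_id <- "twin"
  cams2 <- c(cams["cam1"], list(twin = twin))
  tr <- triangulate_point(list(observation_2d("cam1", uv),
                               observation_2d("twin", uv)), cams2)
  expect_false(tr$reliable)
})

test_that("triangulate_series honors confidence gating and min_views", {
  sim <- sim_quick(duration_s = 2, seed = 3)
  cams <- test_rig()
  views <- render_views(sim$truth$series, cams, seed = 1)
  tri <- triangulate_series(views, cams)
  expect_equal(tri$frames, sim$truth$series$frames)
  expect_lt(max(abs(tri$coords - sim$truth$series$coords), na.rm = TRUE),
            1e-6)

  # zero confidence in one view for 10 frames of one keypoint: still solved
  views2 <- views
  views2[[1]]$confidence[11:20, 3] <- 0
  tri2 <- triangulate_series(views2, cams)
  expect_false(any(tri2$missing[11:20, 3]))
  expect_lt(max(abs(tri2$coords[11:20, 3, ] -
                    sim$truth$series$coords[11:20, 3, ])), 1e-6)

  # all views below the gate at one frame: missing, not interpolated
  views3 <- views
  for (i in seq_along(views3)) views3[[i]]$confidence[5, 2] <- 0.01
  tri3 <- triangulate_series(views3, cams, min_confidence = 0.1)
  expect_true(tri3$missing[5, 2])
  expect_true(all(is.na(tri3$coords[5, 2, ])))
})

test_that("triangulate_series validates view agreement", {
  sim <- sim_quick(duration_s = 2, seed = 3)
  cams <- test_rig()
  views <- render_views(sim$truth$series, cams, seed = 1)
  bad <- views
  bad[[2]]$fps <- 25
  expect_error(triangulate_series(bad, cams), "fps")
  bad2 <- views
  bad2[[2]]$keypoints <- rev(bad2[[2]]$keypoints)
  expect_error(triangulate_series(bad2, cams), "keypoint")
})

test_that("median 3D error is non-decreasing in pixel noise", {
  cams <- test_rig()
  set.seed(4)
  X <- walkway_point(200)
  med <- vapply(c(0, 0.5, 1, 2), function(sg) {
    errs <- vapply(seq_len(nrow(X)), function(i) {
      obs <- lapply(cams, function(c) {
        observation_2d(c$camera_id,
                       project_point(c, X[i, ]) + rnorm(2, 0, sg))
      })
      tr <- triangulate_point(obs, cams)
      sqrt(sum((tr$point - X[i, ])^2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) >= -1e-12))
})

test_that("down-weighting a corrupted view does not hurt accuracy", {
  cams <- test_rig()
  set.seed(5)
  err <- matrix(NA_real_, 120, 2)
  for (i in 1:120) {
    X <- drop(walkway_point())
    uvs <- lapply(cams, function(c) project_point(c, X))
    uvs[[3]] <- uvs[[3]] + rnorm(2, 0, 6)          # corrupted view
    for (j in 1:2) uvs[[j]] <- uvs[[j]] + rnorm(2, 0, 0.5)
    conf_eq <- c(1, 1, 1)
    conf_dw <- c(1, 1, 0.05)
    for (m in 1:2) {
      cf <- if (m == 1) conf_eq else conf_dw
      obs <- lapply(1:3, function(j) {
        observation_2d(cams[[j]]$camera_id, uvs[[j]], cf[j])
      })
      tr <- triangulate_point(obs, cams)
      err[i, m] <- sqrt(sum((tr$point - X)^2))
    }
  }
  expect_lte(median(err[, 2]), median(err[, 1]) + 1e-12)
})
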