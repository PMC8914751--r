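#' Pinhole camera model
#'
#' A calibrated camera is a pinhole model with intrinsics `K` (focal lengths
#' and principal point in pixels), Brown-Conrady lens distortion (radial
#' `k1`, `k2` and tangential `p1`, `p2`), and world-to-camera extrinsics
#' `R`, `t` (meters). A world point `X` maps to the image as
#' `x = K * distort([R t] X / depth)`.
#'
#' @param camera_id identifier string.
#' @param K 3x3 upper-triangular intrinsic matrix; `K[1,1]`, `K[2,2]` are the
#'   focal lengths (pixels) and `K[1,3]`, `K[2,3]` the principal point.
#' @param R 3x3 world-to-camera rotation (orthonormal, det +1, checked to
#'   1e-8).
#' @param t length-3 world-to-camera translation, meters.
#' @param dist distortion coefficients `c(k1, k2, p1, p2)`; defaults to zero.
#' @param image_size `c(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @export
#' @examples
#' cam <- camera_model("cam0", K = intrinsic_matrix(100, 100, 50, 50),
#'                     R = diag(3), t = c(0, 0, 0), image_size = c(100, 100))
#' project_point(cam, c(0, 0, 2))  # principal point: (50, 50)
camera_model <- function(camera_id, K, R, t, dist = c(0, 0, 0, 0),
                         image_size = c(1292, 964)) {
  stopifnot(is.character(camera_id), length(camera_id) == 1L)
  K <- matrix(as.numeric(K), 3, 3)
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3L, length(image_size) == 2L)
  if (K[1, 1] <= 0 || K[2, 2] <= 0) stop("focal lengths must be positive")
  if (any(abs(K[lower.tri(K)]) > 1e-12) || abs(K[3, 3] - 1) > 1e-12) {
    stop("K must be upper-triangular with K[3,3] = 1")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop("R must be orthonormal with determinant +1")
  }
  cx <- K[1, 3]; cy <- K[2, 3]
  if (cx < 0 || cx > image_size[1] || cy < 0 || cy > image_size[2]) {
    stop("principal point outside the image")
  }
  dist <- as.numeric(dist)
  if (length(dist) < 4L) dist <- c(dist, rep(0, 4L - length(dist)))
  structure(list(camera_id = camera_id, K = K, R = R, t = t,
                 dist = dist[1:4], image_size = as.numeric(image_size)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model> ", x$camera_id, ": f = (", x$K[1, 1], ", ", x$K[2, 2],
      ") px, c = (", x$K[1, 3], ", ", x$K[2, 3], "), ",
      x$image_size[1], "x", x$image_size[2],
      if (any(x$dist != 0)) ", distorted" else ", no distortion",
      "\n", sep = "")
  invisible(x)
}

#' Convenience intrinsic matrix
#' @param fx,fy focal lengths (px); @param cx,cy principal point (px);
#' @param skew skew term, default 0.
#' @return 3x3 matrix.
#' @export
intrinsic_matrix <- function(fx, fy, cx, cy, skew = 0) {
  matrix(c(fx, 0, 0, skew, fy, 0, cx, cy, 1), 3, 3)
}

# Brown-Conrady forward distortion of normalized image coordinates (n x 2)
distort_normalized <- function(xy, dist) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x * x + y * y
  radial <- 1 + k1 * r2 + k2 * r2 * r2
  xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x * x)
  yd <- y * radial + p1 * (r2 + 2 * y * y) + 2 * p2 * x * y
  cbind(xd, yd)
}

# invert the distortion by fixed-point iteration (the standard OpenCV scheme)
undistort_normalized <- function(xy, dist, iters = 20L) {
  if (all(dist == 0)) return(xy)
  u <- xy
  for (i in seq_len(iters)) {
    d <- distort_normalized(u, dist)
    u <- u + (xy - d)
  }
  u
}

#' Project world points into a camera
#'
#' @param camera a `camera_model`.
#' @param point length-3 world point (meters), or an `n x 3` matrix.
#' @return `(u, v)` pixel coordinates (length-2 vector, or `n x 2` matrix).
#'   Points at non-positive depth raise an error ("behind camera").
#' @export
project_point <- function(camera, point) {
  X <- if (is.matrix(point)) point else matrix(point, nrow = 1L)
  stopifnot(ncol(X) == 3L)
  Xc <- X %*% t(camera$R) + rep(camera$t, each = nrow(X))
  z <- Xc[, 3]
  if (any(!is.finite(z)) || any(z <= 0)) stop("point behind camera")
  xy <- cbind(Xc[, 1] / z, Xc[, 2] / z)
  xy <- distort_normalized(xy, camera$dist)
  K <- camera$K
  uv <- cbind(K[1, 1] * xy[, 1] + K[1, 2] * xy[, 2] + K[1, 3],
              K[2, 2] * xy[, 2] + K[2, 3])
  colnames(uv) <- c("u", "v")
  if (is.matrix(point)) uv else drop(uv)
}

#' Map pixel coordinates to undistorted normalized image coordinates
#'
#' @param camera a `camera_model`.
#' @param uv length-2 pixel coordinates or `n x 2` matrix.
#' @return Normalized (unit focal length) coordinates of the viewing ray.
#' @export
pixel_to_normalized <- function(camera, uv) {
  p <- if (is.matrix(uv)) uv else matrix(uv, nrow = 1L)
  K <- camera$K
  y <- (p[, 2] - K[2, 3]) / K[2, 2]
  x <- (p[, 1] - K[1, 3] - K[1, 2] * y) / K[1, 1]
  out <- undistort_normalized(cbind(x, y), camera$dist)
  if (is.matrix(uv)) out else drop(out)
}

#' Reprojection error of a world point against an observation
#'
#' @param camera a `camera_model`.
#' @param point length-3 world point.
#' @param observation length-2 pixel observation (or an `observation_2d`).
#' @return Euclidean pixel distance.
#' @export
reprojection_error <- function(camera, point, observation) {
  if (inherits(observation, "observation_2d")) observation <- observation$pixel
  sqrt(sum((project_point(camera, point) - observation)^2))
}

#' A single 2D keypoint observation
#'
#' @param camera_id camera identifier.
#' @param pixel `(u, v)` pixel coordinates (finite).
#' @param confidence optional scalar in `[0, 1]`.
#' @return An `observation_2d`.
#' @export
observation_2d <- function(camera_id, pixel, confidence = NULL) {
  pixel <- as.numeric(pixel)
  stopifnot(length(pixel) == 2L, all(is.finite(pixel)))
  if (!is.null(confidence)) {
    stopifnot(is.finite(confidence), confidence >= 0, confidence <= 1)
  }
  structure(list(camera_id = camera_id, pixel = pixel,
                 confidence = confidence), class = "observation_2d")
}

#' Triangulate a 3D point from multi-view observations
#'
#' Solves the linear DLT system (SVD of the stacked cross-product
#' constraints on the undistorted, normalized observations), then optionally
#' polishes the solution with a damped Gauss-Newton minimization of the
#' confidence-weighted sum of squared reprojection errors.
#'
#' Geometry is flagged degenerate when fewer than two rays subtend more than
#' `min_ray_angle_deg`, or when the DLT design matrix has condition number
#' above `max_condition`; the point is still returned with
#' `reliable = FALSE`.
#'
#' @param observations list of `observation_2d` from at least two distinct
#'   cameras.
#' @param cameras named list of `camera_model` (names = camera ids).
#' @param refine logical; run the nonlinear refinement (default TRUE).
#' @param min_ray_angle_deg,max_condition degeneracy thresholds.
#' @return List with `point` (length-3), `rms_reprojection_error` (pixels),
#'   `reliable` (logical), `n_views`.
#' @export
triangulate_point <- function(observations, cameras, refine = TRUE,
                              min_ray_angle_deg = 1, max_condition = 1e8) {
  ids <- vapply(observations, function(o) o$camera_id, character(1))
  if (length(unique(ids)) < 2L) {
    stop("insufficient views: need observations from >= 2 distinct cameras")
  }
  cams <- lapply(ids, function(id) {
    cam <- cameras[[id]]
    if (is.null(cam)) stop("no calibration for camera '", id, "'")
    cam
  })
  uv <- do.call(rbind, lapply(observations, function(o) o$pixel))
  w <- vapply(observations, function(o) {
    if (is.null(o$confidence)) 1 else o$confidence
  }, numeric(1))
  xyn <- do.call(rbind, lapply(seq_along(cams), function(i) {
    matrix(pixel_to_normalized(cams[[i]], uv[i, ]), nrow = 1L)
  }))

  # DLT on normalized coordinates: rows x*P3 - P1, y*P3 - P2, P = [R | t]
  A <- do.call(rbind, lapply(seq_along(cams), function(i) {
    P <- cbind(cams[[i]]$R, cams[[i]]$t)
    sw <- sqrt(w[i])
    rbind(sw * (xyn[i, 1] * P[3, ] - P[1, ]),
          sw * (xyn[i, 2] * P[3, ] - P[2, ]))
  }))
  sv <- svd(A)
  Xh <- sv$v[, 4]
  # sigma4 ~ 0 for consistent observations; geometric conditioning is the
  # spread of the first three singular values (parallel rays -> sigma3 ~ 0)
  cond <- sv$d[1] / max(sv$d[3], .Machine$double.xmin)
  if (abs(Xh[4]) < 1e-14) {
    X <- Xh[1:3]  # point at infinity; will be flagged unreliable below
    cond <- Inf
  } else {
    X <- Xh[1:3] / Xh[4]
  }

  # ray-angle degeneracy: max pairwise angle between viewing rays
  rays <- t(vapply(seq_along(cams), function(i) {
    r <- t(cams[[i]]$R) %*% c(xyn[i, ], 1)
    r / sqrt(sum(r^2))
  }, numeric(3)))
  max_ang <- 0
  for (i in seq_len(nrow(rays) - 1L)) {
    for (j in (i + 1L):nrow(rays)) {
      ca <- min(1, max(-1, abs(sum(rays[i, ] * rays[j, ]))))
      max_ang <- max(max_ang, acos(ca) * 180 / pi)
    }
  }
  reliable <- is.finite(cond) && cond <= max_condition &&
    max_ang >= min_ray_angle_deg

  if (refine && reliable) {
    X <- gauss_newton_point(X, cams, xyn, w)
  }
  rms <- point_rms_error(X, cams, uv, w)
  list(point = X, rms_reprojection_error = rms, reliable = reliable,
       n_views = length(unique(ids)))
}

# damped Gauss-Newton on the normalized-coordinate residuals
gauss_newton_point <- function(X, cams, xyn, w, iters = 10L) {
  cost <- function(X) {
    s <- 0
    for (i in seq_along(cams)) {
      Xc <- cams[[i]]$R %*% X + cams[[i]]$t
      if (Xc[3] <= 0) return(Inf)
      s <- s + w[i] * sum((Xc[1:2] / Xc[3] - xyn[i, ])^2)
    }
    s
  }
  lambda <- 1e-6
  f0 <- cost(X)
  for (it in seq_len(iters)) {
    JtJ <- matrix(0, 3, 3)
    Jtr <- numeric(3)
    for (i in seq_along(cams)) {
      Rm <- cams[[i]]$R
      Xc <- Rm %*% X + cams[[i]]$t
      z <- Xc[3]
      if (z <= 0) return(X)
      r <- c(Xc[1] / z - xyn[i, 1], Xc[2] / z - xyn[i, 2])
      # d(x/z)/dX = (R1 - x/z R3)/z etc.
      J <- rbind((Rm[1, ] - (Xc[1] / z) * Rm[3, ]) / z,
                 (Rm[2, ] - (Xc[2] / z) * Rm[3, ]) / z)
      JtJ <- JtJ + w[i] * crossprod(J)
      Jtr <- Jtr + w[i] * drop(crossprod(J, r))
    }
    step <- tryCatch(solve(JtJ + lambda * diag(3), -Jtr),
                     error = function(e) NULL)
    if (is.null(step)) break
    Xn <- X + step
    fn <- cost(Xn)
    if (is.finite(fn) && fn <= f0) {
      if (f0 - fn < 1e-16 * (1 + f0)) { X <- Xn; break }
      X <- Xn; f0 <- fn; lambda <- lambda / 3
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  X
}

point_rms_error <- function(X, cams, uv, w) {
  e2 <- vapply(seq_along(cams), function(i) {
    Xc <- cams[[i]]$R %*% X + cams[[i]]$t
    if (Xc[3] <= 0) return(Inf)
    sum((project_point(cams[[i]], X) - uv[i, ])^2)
  }, numeric(1))
  sqrt(stats::weighted.mean(e2, w))
}

#' Triangulate per-frame, per-keypoint 3D trajectories from multiple views
#'
#' For every frame and keypoint, observations with confidence at or above
#' `min_confidence` are triangulated; samples seen by fewer than `min_views`
#' qualifying cameras are marked missing (never interpolated here).
#'
#' @param views list of `kps2d`, one per camera, sharing fps, frame count and
#'   keypoint set.
#' @param cameras named list of `camera_model`.
#' @param min_confidence confidence gate in `[0, 1]` (default 0.1).
#' @param min_views minimum qualifying views (default 2).
#' @param refine nonlinear refinement flag, passed to [triangulate_point()].
#' @param vertical_axis vertical axis label for the output series.
#' @param confidence_weighted weight the solve by detection confidence
#'   (default TRUE).
#' @return A `kps3d` with the same frame count; attribute `"rms"` holds the
#'   per-sample RMS reprojection error and attribute `"unreliable"` a logical
#'   matrix of degeneracy flags.
#' @export
triangulate_series <- function(views, cameras, min_confidence = 0.1,
                               min_views = 2L, refine = TRUE,
                               vertical_axis = "Y",
                               confidence_weighted = TRUE) {
  stopifnot(length(views) >= 2L)
  fps <- views[[1]]$fps
  frames <- views[[1]]$frames
  kp <- views[[1]]$keypoints
  for (v in views) {
    if (v$fps != fps) stop("views disagree on fps")
    if (v$frames != frames) stop("views disagree on frame count")
    if (!identical(v$keypoints, kp)) stop("views disagree on keypoint set")
  }
  cams <- lapply(views, function(v) {
    cam <- cameras[[v$camera_id]]
    if (is.null(cam)) stop("no calibration for camera '", v$camera_id, "'")
    cam
  })
  nv <- length(views)
  K <- length(kp)
  co <- array(NA_real_, c(frames, K, 3))
  rms <- matrix(NA_real_, frames, K)
  unrel <- matrix(FALSE, frames, K)
  for (f in seq_len(frames)) {
    for (k in seq_len(K)) {
      obs <- vector("list", nv)
      n <- 0L
      for (i in seq_len(nv)) {
        v <- views[[i]]
        if (v$missing[f, k]) next
        cf <- v$confidence[f, k]
        if (is.na(cf) || cf < min_confidence) next
        n <- n + 1L
        obs[[n]] <- observation_2d(v$camera_id, v$coords[f, k, ],
                                   if (confidence_weighted) cf else NULL)
      }
      if (n < min_views) next
      tr <- triangulate_point(obs[seq_len(n)], cameras, refine = refine)
      co[f, k, ] <- tr$point
      rms[f, k] <- tr$rms_reprojection_error
      unrel[f, k] <- !tr$reliable
    }
  }
  out <- keypoint_series_3d(co, fps, keypoints = kp,
                            vertical_axis = vertical_axis,
                            skeleton = views[[1]]$skeleton)
  attr(out, "rms") <- rms
  attr(out, "unreliable") <- unrel
  out
}
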