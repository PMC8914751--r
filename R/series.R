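#' Time-indexed keypoint trajectories
#'
#' `keypoint_series_3d()` holds world-space trajectories (meters) as a
#' `frames x keypoints x 3` array plus a per-sample missing mask;
#' `keypoint_series_2d()` holds per-view pixel detections with confidences
#' as a `frames x keypoints x 2` array plus a confidence matrix. Frames are
#' 0-based; sample `i` (R index) is at time `(i - 1) / fps` seconds.
#'
#' @param coords numeric array, `frames x keypoints x 3` (meters) or
#'   `frames x keypoints x 2` (pixels). NA coordinates mark missing samples.
#' @param fps sampling rate in Hz, > 0.
#' @param keypoints character vector of keypoint names (defaults to the
#'   dimnames of `coords`).
#' @param missing optional logical `frames x keypoints` matrix; derived from
#'   NA coordinates when absent.
#' @param vertical_axis which world axis is "up": `"X"`, `"Y"` or `"Z"`.
#'   Defaults to `"Y"`.
#' @param skeleton a `gait_skeleton` or bundled skeleton name; optional but
#'   required by the gait stages, which resolve heel/toe/hip roles through it.
#' @param confidence numeric `frames x keypoints` matrix in `[0, 1]` (2D only).
#' @param camera_id camera identifier string (2D only).
#' @return An object of class `kps3d` or `kps2d`.
#' @export
keypoint_series_3d <- function(coords, fps, keypoints = NULL, missing = NULL,
                               vertical_axis = "Y", skeleton = NULL) {
  coords <- as_coord_array(coords, 3L, keypoints)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a positive scalar")
  }
  vertical_axis <- match.arg(vertical_axis, c("X", "Y", "Z"))
  miss <- resolve_missing(coords, missing)
  coords[rep(miss, dim(coords)[3])] <- NA_real_
  if (!is.null(skeleton)) {
    skeleton <- as_skeleton(skeleton)
    unknown <- setdiff(dimnames(coords)[[2]], skeleton$keypoints)
    if (length(unknown)) {
      stop("keypoints not in skeleton '", skeleton$name, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(coords = coords, fps = fps, frames = dim(coords)[1],
                 keypoints = dimnames(coords)[[2]], missing = miss,
                 vertical_axis = vertical_axis, skeleton = skeleton),
            class = "kps3d")
}

#' @rdname keypoint_series_3d
#' @export
keypoint_series_2d <- function(coords, fps, camera_id, keypoints = NULL,
                               confidence = NULL, missing = NULL,
                               skeleton = NULL) {
  coords <- as_coord_array(coords, 2L, keypoints)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a positive scalar")
  }
  stopifnot(is.character(camera_id), length(camera_id) == 1L)
  miss <- resolve_missing(coords, missing)
  coords[rep(miss, 2L)] <- NA_real_
  if (is.null(confidence)) {
    confidence <- matrix(1, dim(coords)[1], dim(coords)[2])
  }
  confidence <- as.matrix(confidence)
  stopifnot(all(dim(confidence) == dim(coords)[1:2]))
  ok <- is.finite(confidence)
  if (any(confidence[ok] < 0 | confidence[ok] > 1)) {
    stop("confidence values must lie in [0, 1]")
  }
  confidence[miss] <- NA_real_
  dimnames(confidence) <- dimnames(coords)[1:2]
  if (!is.null(skeleton)) skeleton <- as_skeleton(skeleton)
  structure(list(coords = coords, fps = fps, frames = dim(coords)[1],
                 keypoints = dimnames(coords)[[2]], camera_id = camera_id,
                 confidence = confidence, missing = miss,
                 skeleton = skeleton),
            class = "kps2d")
}

as_coord_array <- function(coords, d, keypoints) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != d) {
    stop("coords must be a frames x keypoints x ", d, " array")
  }
  storage.mode(coords) <- "double"
  kp <- if (!is.null(keypoints)) keypoints else dimnames(coords)[[2]]
  if (is.null(kp)) kp <- paste0("kp", seq_len(dim(coords)[2]))
  if (length(kp) != dim(coords)[2]) stop("keypoint names do not match coords")
  dimnames(coords) <- list(NULL, kp, c("x", "y", "z")[seq_len(d)])
  coords
}

resolve_missing <- function(coords, missing) {
  derived <- apply(is.na(coords), c(1, 2), any)
  if (is.null(missing)) {
    miss <- derived
  } else {
    miss <- as.matrix(missing) | derived
  }
  storage.mode(miss) <- "logical"
  dimnames(miss) <- dimnames(coords)[1:2]
  miss
}

#' @export
print.kps3d <- function(x, ...) {
  cat("<kps3d> ", x$frames, " frames x ", length(x$keypoints),
      " keypoints @ ", x$fps, " fps, up = ", x$vertical_axis,
      ", missing = ", sum(x$missing), " samples\n", sep = "")
  invisible(x)
}

#' @export
print.kps2d <- function(x, ...) {
  cat("<kps2d> [", x$camera_id, "] ", x$frames, " frames x ",
      length(x$keypoints), " keypoints @ ", x$fps, " fps, missing = ",
      sum(x$missing), " samples\n", sep = "")
  invisible(x)
}

#' Extract one keypoint's trajectory as a frames x 3 matrix
#'
#' @param series a `kps3d`.
#' @param keypoint keypoint name or gait role (roles are resolved through the
#'   series skeleton when a name match fails).
#' @return Numeric `frames x 3` matrix (NA where missing).
#' @export
kp_traj <- function(series, keypoint) {
  stopifnot(inherits(series, "kps3d"))
  if (!(keypoint %in% series$keypoints)) {
    if (!is.null(series$skeleton)) {
      kp <- role_keypoint(series$skeleton, keypoint, required = FALSE)
      if (!is.null(kp) && kp %in% series$keypoints) keypoint <- kp
      else stop("unknown keypoint or role '", keypoint, "'")
    } else stop("unknown keypoint '", keypoint, "'")
  }
  m <- series$coords[, keypoint, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m
}

#' Index of the vertical (up) world axis
#' @param series a `kps3d`.
#' @return 1, 2 or 3.
#' @export
vertical_index <- function(series) {
  match(series$vertical_axis, c("X", "Y", "Z"))
}

#' Re-express a 3D series in canonical Y-up axes
#'
#' Permutes the world axes so the declared vertical axis becomes Y while
#' keeping a right-handed frame; downstream computations are invariant to the
#' original axis convention once this mapping is applied.
#'
#' @param series a `kps3d`.
#' @return A `kps3d` with `vertical_axis = "Y"`.
#' @export
canonicalize_axes <- function(series) {
  stopifnot(inherits(series, "kps3d"))
  if (series$vertical_axis == "Y") return(series)
  # cyclic permutations keep the frame right-handed
  perm <- switch(series$vertical_axis,
                 Z = c(2L, 3L, 1L),   # (x,y,z) -> (y,z,x): old Z becomes new Y
                 X = c(3L, 1L, 2L))   # old X becomes new Y
  co <- series$coords[, , perm, drop = FALSE]
  keypoint_series_3d(co, series$fps, missing = series$missing,
                     vertical_axis = "Y", skeleton = series$skeleton)
}

#' Apply a rigid transform (rotation + translation) to a 3D series
#'
#' @param series a `kps3d`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return Transformed `kps3d`.
#' @export
transform_series <- function(series, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(series, "kps3d"))
  d <- dim(series$coords)
  flat <- matrix(aperm(series$coords, c(3, 1, 2)), nrow = 3L)
  flat <- rotation %*% flat + translation
  co <- aperm(array(flat, c(3, d[1], d[2])), c(2, 3, 1))
  keypoint_series_3d(co, series$fps, keypoints = series$keypoints,
                     missing = series$missing,
                     vertical_axis = series$vertical_axis,
                     skeleton = series$skeleton)
}

#' Restrict a series to a frame window
#' @param series `kps3d`; @param from,to 1-based R frame indices (inclusive).
#' @return `kps3d` with `to - from + 1` frames.
#' @export
crop_series <- function(series, from, to) {
  stopifnot(inherits(series, "kps3d"), from >= 1, to <= series$frames, from <= to)
  keypoint_series_3d(series$coords[from:to, , , drop = FALSE], series$fps,
                     missing = series$missing[from:to, , drop = FALSE],
                     vertical_axis = series$vertical_axis,
                     skeleton = series$skeleton)
}
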