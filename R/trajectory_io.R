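#' Keypoint trajectory CSV files
#'
#' Trajectories travel as plain UTF-8 CSV with leading `# key=value`
#' metadata lines, a header row, and one row per (frame, keypoint) sample.
#' Frames are 0-based integers; absent rows are missing samples. 2D files
#' carry `frame,keypoint,u,v,confidence` plus `# fps=` and `# camera_id=`;
#' 3D files carry `frame,keypoint,x,y,z` plus `# fps=`, `# units=` (`m` or
#' `mm`, converted to meters on read) and `# vertical_axis=`. Coordinates
#' are written with 17 significant digits, so write -> read round-trips are
#' exact at double precision.
#'
#' @param path file path.
#' @param skeleton optional `gait_skeleton` or bundled name; when given, file
#'   keypoints are validated against it and ordered canonically.
#' @return `read_keypoints_2d` a [keypoint_series_2d()];
#'   `read_keypoints_3d` a [keypoint_series_3d()].
#' @export
read_keypoints_2d <- function(path, skeleton = NULL) {
  parsed <- read_csv_meta(path)
  meta <- parsed$meta
  for (field in c("fps", "camera_id")) {
    if (is.null(meta[[field]])) {
      stop("file '", path, "' is missing required metadata field '",
           field, "'")
    }
  }
  df <- parsed$data
  need <- c("frame", "keypoint", "u", "v")
  if (!all(need %in% names(df))) {
    stop("2D keypoint CSV must have columns frame,keypoint,u,v[,confidence]")
  }
  if (is.null(df$confidence)) df$confidence <- 1
  layout <- series_layout(df, meta, skeleton)
  co <- array(NA_real_, c(layout$frames, length(layout$kp), 2))
  cf <- matrix(NA_real_, layout$frames, length(layout$kp))
  fi <- df$frame + 1L
  ki <- match(df$keypoint, layout$kp)
  co[cbind(fi, ki, 1L)] <- df$u
  co[cbind(fi, ki, 2L)] <- df$v
  cf[cbind(fi, ki)] <- df$confidence
  cf[is.na(cf)] <- 0
  keypoint_series_2d(co, fps = as.numeric(meta$fps),
                     camera_id = meta$camera_id, keypoints = layout$kp,
                     confidence = cf, skeleton = skeleton)
}

#' @rdname read_keypoints_2d
#' @param series the series to write.
#' @export
write_keypoints_2d <- function(series, path) {
  stopifnot(inherits(series, "kps2d"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# fps=%s", num17(series$fps)),
               sprintf("# camera_id=%s", series$camera_id),
               sprintf("# frames=%d", series$frames),
               "frame,keypoint,u,v,confidence"), con)
  for (k in seq_along(series$keypoints)) {
    keep <- which(!series$missing[, k])
    if (!length(keep)) next
    writeLines(sprintf("%d,%s,%s,%s,%s", keep - 1L, series$keypoints[k],
                       num17(series$coords[keep, k, 1]),
                       num17(series$coords[keep, k, 2]),
                       num17(series$confidence[keep, k])), con)
  }
  invisible(path)
}

#' @rdname read_keypoints_2d
#' @export
read_keypoints_3d <- function(path, skeleton = NULL) {
  parsed <- read_csv_meta(path)
  meta <- parsed$meta
  if (is.null(meta$fps)) {
    stop("file '", path, "' is missing required metadata field 'fps'")
  }
  units <- if (is.null(meta$units)) "m" else meta$units
  if (!units %in% c("m", "mm")) stop("units must be 'm' or 'mm'")
  if (units == "mm") {
    message("converting '", path, "' coordinates from mm to m")
  }
  scale <- if (units == "mm") 1e-3 else 1
  vax <- if (is.null(meta$vertical_axis)) "Y" else toupper(meta$vertical_axis)
  df <- parsed$data
  need <- c("frame", "keypoint", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("3D keypoint CSV must have columns frame,keypoint,x,y,z")
  }
  layout <- series_layout(df, meta, skeleton)
  co <- array(NA_real_, c(layout$frames, length(layout$kp), 3))
  fi <- df$frame + 1L
  ki <- match(df$keypoint, layout$kp)
  co[cbind(fi, ki, 1L)] <- df$x * scale
  co[cbind(fi, ki, 2L)] <- df$y * scale
  co[cbind(fi, ki, 3L)] <- df$z * scale
  keypoint_series_3d(co, fps = as.numeric(meta$fps), keypoints = layout$kp,
                     vertical_axis = vax, skeleton = skeleton)
}

#' @rdname read_keypoints_2d
#' @export
write_keypoints_3d <- function(series, path) {
  stopifnot(inherits(series, "kps3d"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# fps=%s", num17(series$fps)),
               "# units=m",
               sprintf("# vertical_axis=%s", series$vertical_axis),
               sprintf("# frames=%d", series$frames),
               "frame,keypoint,x,y,z"), con)
  for (k in seq_along(series$keypoints)) {
    keep <- which(!series$missing[, k])
    if (!length(keep)) next
    writeLines(sprintf("%d,%s,%s,%s,%s", keep - 1L, series$keypoints[k],
                       num17(series$coords[keep, k, 1]),
                       num17(series$coords[keep, k, 2]),
                       num17(series$coords[keep, k, 3])), con)
  }
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)

read_csv_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta & seq_along(lines) <= which.max(!is_meta) - 1L]
  if (!any(!is_meta)) meta_lines <- lines[is_meta]
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[trimws(substr(kv, 1, eq - 1))]] <-
        trimws(substr(kv, eq + 1, nchar(kv)))
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("file '", path, "' has no data rows")
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$frame != floor(df$frame)) || any(df$frame < 0)) {
      stop("frame indices must be non-negative integers")
    }
  }
  list(meta = meta, data = df)
}

series_layout <- function(df, meta, skeleton) {
  kp <- unique(df$keypoint)
  if (!is.null(skeleton)) {
    skeleton <- as_skeleton(skeleton)
    unknown <- setdiff(kp, skeleton$keypoints)
    if (length(unknown)) {
      stop("unknown keypoints for skeleton '", skeleton$name, "': ",
           paste(unknown, collapse = ", "))
    }
    kp <- intersect(skeleton$keypoints, kp)
  }
  # rows must be grouped by keypoint or frame-sorted; reject frame indices
  # that go backwards within one keypoint (corrupt/unsorted file)
  for (k in kp) {
    fr <- df$frame[df$keypoint == k]
    if (is.unsorted(fr, strictly = TRUE)) {
      stop("non-monotone frame indices for keypoint '", k, "'")
    }
  }
  frames <- if (!is.null(meta$frames)) as.integer(meta$frames)
            else max(df$frame) + 1L
  if (frames < max(df$frame) + 1L) stop("frame index exceeds declared frames")
  list(kp = kp, frames = frames)
}

#' Write a TRC marker-trajectory file (OpenSim interoperability)
#'
#' Emits the tab-delimited TRC format consumed by OpenSim's Scaling and
#' Inverse Kinematics tools, so users can run a musculoskeletal-model
#' pipeline on trajectories produced here. TRC has no missing-sample
#' concept: interpolate first (see [interpolate_gaps()]).
#'
#' @param series a `kps3d` with no missing samples.
#' @param path output path.
#' @param units coordinate units to write, `"m"` (default) or `"mm"`.
#' @return `path`, invisibly.
#' @export
write_trc <- function(series, path, units = c("m", "mm")) {
  stopifnot(inherits(series, "kps3d"))
  units <- match.arg(units)
  if (any(series$missing)) {
    stop("series has missing samples; interpolate_gaps() before write_trc()")
  }
  scale <- if (units == "mm") 1000 else 1
  n <- series$frames
  K <- length(series$keypoints)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%.6f\t%.6f\t%d\t%d\t%s\t%.6f\t%d\t%d",
                     series$fps, series$fps, n, K, units, series$fps, 1L, n),
             con)
  hdr <- c("Frame#", "Time",
           as.vector(rbind(series$keypoints, "", "")))
  writeLines(paste(hdr, collapse = "\t"), con)
  sub <- c("", "", as.vector(vapply(seq_len(K), function(k) {
    paste0(c("X", "Y", "Z"), k)
  }, character(3))))
  writeLines(paste(sub, collapse = "\t"), con)
  writeLines("", con)
  tm <- (seq_len(n) - 1L) / series$fps
  flat <- matrix(aperm(series$coords * scale, c(3, 2, 1)), nrow = 3 * K)
  rows <- vapply(seq_len(n), function(f) {
    paste(c(sprintf("%d", f), sprintf("%.9f", tm[f]),
            sprintf("%.8f", flat[, f])), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}
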