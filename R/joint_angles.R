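#' Anatomical pelvis frame at one frame
#'
#' Builds a right-handed (forward, up, lateral) frame from the keypoints:
#' the lateral axis follows the right-hip to left-hip vector, the up axis
#' follows the pelvis-root to trunk segment when the skeleton binds a
#' `trunk` role (without a trunk reference, pelvic tilt is unobservable
#' from the hip keypoints alone and the world vertical is used), and
#' forward = up x lateral, adjusted to point along the progression
#' direction.
#'
#' @param series a `kps3d` with hip and pelvis-root roles.
#' @param frame 1-based frame index.
#' @param progression optional unit 3-vector fixing the forward sign;
#'   default from [walking_direction()].
#' @return List of unit 3-vectors `forward`, `up`, `lateral` (lateral
#'   points to the subject's left).
#' @export
pelvis_frame <- function(series, frame, progression = NULL) {
  lh <- kp_traj(series, "left_hip")[frame, ]
  rh <- kp_traj(series, "right_hip")[frame, ]
  lat <- lh - rh
  nl <- sqrt(sum(lat^2))
  if (nl < 1e-9) stop("hips coincide: pelvis frame undefined")
  lat <- lat / nl
  up <- numeric(3); up[vertical_index(series)] <- 1
  if (!is.null(series$skeleton) &&
      !is.null(series$skeleton$roles$trunk) &&
      series$skeleton$roles$trunk %in% series$keypoints) {
    tr <- kp_traj(series, "trunk")[frame, ]
    root <- kp_traj(series, "pelvis_root")[frame, ]
    cand <- tr - root
    if (sqrt(sum(cand^2)) > 1e-9) up <- cand / sqrt(sum(cand^2))
  }
  # orthonormalize: keep up, project lateral off it
  lat <- lat - sum(lat * up) * up
  lat <- lat / sqrt(sum(lat^2))
  fwd <- cross3(up, lat)
  if (is.null(progression)) {
    progression <- tryCatch(walking_direction(series)$progression,
                            error = function(e) NULL)
  }
  if (!is.null(progression) && sum(fwd * progression) < 0) {
    lat <- -lat
    fwd <- -fwd
  }
  list(forward = unname(fwd), up = unname(up), lateral = unname(lat))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Joint-angle curves over one gait cycle
#'
#' Computes the five lower-body angle curves directly from keypoint
#' geometry (no musculoskeletal model), per frame of the cycle, then
#' time-normalized to 101 nodes (0-100% of the cycle):
#'
#' * `hip_flexion`: signed angle of the thigh (hip to knee) against the
#'   pelvis down axis, in the pelvis sagittal plane; thigh forward
#'   positive.
#' * `knee_flexion`: 180 degrees minus the angle at the knee between the
#'   thigh and the shank; full extension = 0, flexion positive.
#' * `ankle_dorsiflexion`: signed sagittal angle between the foot (heel to
#'   toe) and shank (knee to ankle) vectors, minus the same angle at the
#'   cycle's mid-stance (foot flat) so that dorsiflexion is ~0 at foot
#'   flat and positive when the toes pull up; `ankle_reference =
#'   "absolute"` skips the offset.
#' * `hip_abduction`: signed angle of the thigh in the pelvis frontal
#'   plane, away from the midline positive.
#' * `pelvis_tilt`: angle of the pelvis forward axis below the horizontal,
#'   anterior tilt positive.
#'
#' @param series a `kps3d` with the lower-body roles bound.
#' @param cycle a [gait_cycle()].
#' @param cutoff_hz kinematics low-pass cutoff (default 12 Hz).
#' @param prefiltered series already interpolated + filtered?
#' @param ankle_reference `"midstance"` (default) or `"absolute"`.
#' @param max_missing_frac error when more than this fraction of any
#'   required keypoint is missing within the cycle (default 0.2).
#' @return A `joint_angle_curves` object: list with `side`, `cycle`,
#'   `curves` (named list of five length-101 numeric vectors, degrees) and
#'   `conventions`.
#' @export
compute_joint_angles <- function(series, cycle, cutoff_hz = 12,
                                 prefiltered = FALSE,
                                 ankle_reference = c("midstance", "absolute"),
                                 max_missing_frac = 0.2) {
  stopifnot(inherits(series, "kps3d"), inherits(cycle, "gait_cycle"))
  ankle_reference <- match.arg(ankle_reference)
  side <- cycle$side
  roles <- c(paste0(side, c("_hip", "_knee", "_ankle", "_heel", "_toe")),
             "left_hip", "right_hip", "pelvis_root")
  i0 <- cycle$start_frame + 1L
  i1 <- cycle$end_frame + 1L
  for (r in roles) {
    kp <- role_keypoint(series$skeleton, r)
    frac <- mean(series$missing[i0:i1, kp])
    if (frac > max_missing_frac) {
      stop("keypoint '", kp, "' missing for ", round(100 * frac),
           "% of the cycle")
    }
  }
  fser <- prepare_kinematics(series, cutoff_hz, prefiltered)
  prog <- walking_direction(fser)$progression

  hip <- kp_traj(fser, paste0(side, "_hip"))[i0:i1, , drop = FALSE]
  knee <- kp_traj(fser, paste0(side, "_knee"))[i0:i1, , drop = FALSE]
  ank <- kp_traj(fser, paste0(side, "_ankle"))[i0:i1, , drop = FALSE]
  heel <- kp_traj(fser, paste0(side, "_heel"))[i0:i1, , drop = FALSE]
  toe <- kp_traj(fser, paste0(side, "_toe"))[i0:i1, , drop = FALSE]

  nfr <- i1 - i0 + 1L
  hipf <- kneef <- ankf <- hipa <- tilt <- numeric(nfr)
  sgn_out <- if (side == "right") -1 else 1   # lateral axis points left
  for (j in seq_len(nfr)) {
    pf <- pelvis_frame(fser, i0 + j - 1L, progression = prog)
    down <- -pf$up
    thigh <- knee[j, ] - hip[j, ]
    shank <- ank[j, ] - knee[j, ]
    foot <- toe[j, ] - heel[j, ]
    hipf[j] <- atan2(sum(thigh * pf$forward), sum(thigh * down)) * 180 / pi
    kneef[j] <- 180 - angle_between_rows(matrix(-thigh, 1), matrix(shank, 1))
    hipa[j] <- atan2(sgn_out * sum(thigh * pf$lateral),
                     sum(thigh * down)) * 180 / pi
    up_w <- numeric(3); up_w[vertical_index(fser)] <- 1
    tilt[j] <- asin(min(1, max(-1, -sum(pf$forward * up_w)))) * 180 / pi
    ankf[j] <- sagittal_signed_angle(matrix(foot, 1), matrix(shank, 1),
                                     matrix(pf$forward, 1), matrix(pf$up, 1))
  }
  if (ankle_reference == "midstance") {
    # neutral frame = strike + half the stance duration (rounded to the
    # frame grid; foot flat)
    mid <- round((cycle$toe_off_frame - cycle$start_frame) / 2) + 1L
    mid <- min(max(mid, 1L), nfr)
    ankf <- ankf - ankf[mid]
  }
  curves <- list(hip_flexion = time_normalize(hipf),
                 knee_flexion = time_normalize(kneef),
                 ankle_dorsiflexion = time_normalize(ankf),
                 hip_abduction = time_normalize(hipa),
                 pelvis_tilt = time_normalize(tilt))
  structure(list(side = side, cycle = cycle, curves = curves,
                 conventions = list(
                   flexion = "positive", dorsiflexion = "positive",
                   abduction = "positive", anterior_tilt = "positive",
                   ankle_reference = ankle_reference)),
            class = "joint_angle_curves")
}

#' @export
print.joint_angle_curves <- function(x, ...) {
  cat("<joint_angle_curves> ", x$side, " cycle frames ",
      x$cycle$start_frame, "-", x$cycle$end_frame, "\n", sep = "")
  for (nm in names(x$curves)) {
    cat(sprintf("  %-20s range [%7.2f, %7.2f] deg\n", nm,
                min(x$curves[[nm]]), max(x$curves[[nm]])))
  }
  invisible(x)
}

#' Joint angles for every cycle of a record
#'
#' @inheritParams compute_joint_angles
#' @param cycles list of cycles; default [segment_cycles()].
#' @return List of `joint_angle_curves`.
#' @export
compute_joint_angles_all <- function(series, cycles = NULL, cutoff_hz = 12,
                                     ...) {
  if (is.null(cycles)) cycles <- segment_cycles(series)
  fser <- prepare_kinematics(series, cutoff_hz, FALSE)
  lapply(cycles, function(cy) {
    compute_joint_angles(fser, cy, prefiltered = TRUE, ...)
  })
}

#' Long-format angle table (cycle id, side, angle, node, value)
#'
#' @param angle_list list of `joint_angle_curves`.
#' @param path optional CSV output path.
#' @param layout `"long"` (default) or `"wide"` (101 node columns).
#' @return data.frame.
#' @export
angles_table <- function(angle_list, path = NULL,
                         layout = c("long", "wide")) {
  layout <- match.arg(layout)
  rows <- list()
  for (ci in seq_along(angle_list)) {
    a <- angle_list[[ci]]
    for (nm in names(a$curves)) {
      if (layout == "long") {
        rows[[length(rows) + 1L]] <- data.frame(
          cycle = ci, side = a$side, angle = nm, node = 0:100,
          value_deg = a$curves[[nm]])
      } else {
        w <- as.data.frame(t(a$curves[[nm]]))
        names(w) <- paste0("node", 0:100)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(cycle = ci, side = a$side, angle = nm), w)
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
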