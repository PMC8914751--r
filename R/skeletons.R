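#' Skeleton definitions
#'
#' A skeleton names the ordered keypoint set of a motion-capture protocol,
#' its laterality tags, the bone (segment) topology, and the binding of
#' anatomical *roles* needed for gait analysis (which keypoint is the left
#' heel, which is the pelvis root, ...). Two skeletons ship with the package:
#' `"h36m21"`, the 17 Human3.6M body joints extended with heels and toes
#' (21 keypoints, the markerless set), and `"davis22"`, the 22-marker Davis
#' lower-body protocol used by marker-based systems.
#'
#' @param name skeleton name (string).
#' @param keypoints character vector of unique keypoint names.
#' @param side character vector, one of `"left"`, `"right"`, `"center"` per
#'   keypoint.
#' @param bones two-column character matrix of keypoint-name pairs.
#' @param roles named list binding role names (e.g. `left_heel`,
#'   `pelvis_root`, `head_top`, `head_base`) to keypoint names. Roles are
#'   optional, but a bound role must name an existing keypoint.
#' @return An object of class `gait_skeleton`.
#' @export
#' @examples
#' sk <- skeleton_h36m21()
#' sk$roles$left_heel
skeleton_definition <- function(name, keypoints, side, bones = NULL,
                                roles = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (anyDuplicated(keypoints)) {
    stop("skeleton '", name, "': duplicated keypoint names")
  }
  if (length(side) != length(keypoints) ||
      !all(side %in% c("left", "right", "center"))) {
    stop("side must be left/right/center, one per keypoint")
  }
  if (!is.null(bones)) {
    bones <- as.matrix(bones)
    if (ncol(bones) != 2L) stop("bones must have two columns")
    bad <- setdiff(as.vector(bones), keypoints)
    if (length(bad)) stop("bone endpoints not in keypoint set: ",
                          paste(bad, collapse = ", "))
  }
  for (r in names(roles)) {
    if (!is.null(roles[[r]]) && !(roles[[r]] %in% keypoints)) {
      stop("role '", r, "' bound to unknown keypoint '", roles[[r]], "'")
    }
  }
  structure(list(name = name, keypoints = keypoints,
                 side = stats::setNames(side, keypoints),
                 bones = bones, roles = roles),
            class = "gait_skeleton")
}

#' @export
print.gait_skeleton <- function(x, ...) {
  cat("<gait_skeleton> ", x$name, ": ", length(x$keypoints), " keypoints, ",
      if (is.null(x$bones)) 0L else nrow(x$bones), " bones, ",
      length(x$roles), " bound roles\n", sep = "")
  invisible(x)
}

#' @describeIn skeleton_definition Human3.6M joints plus heels and toes
#'   (21 keypoints), the default markerless skeleton.
#' @export
skeleton_h36m21 <- function() {
  kp <- c("pelvis",
          "right_hip", "right_knee", "right_ankle", "right_heel", "right_toe",
          "left_hip", "left_knee", "left_ankle", "left_heel", "left_toe",
          "spine", "neck", "head", "nose",
          "left_shoulder", "left_elbow", "left_wrist",
          "right_shoulder", "right_elbow", "right_wrist")
  side <- c("center",
            rep("right", 5), rep("left", 5),
            "center", "center", "center", "center",
            rep("left", 3), rep("right", 3))
  bones <- rbind(
    c("pelvis", "right_hip"), c("right_hip", "right_knee"),
    c("right_knee", "right_ankle"), c("right_ankle", "right_heel"),
    c("right_heel", "right_toe"),
    c("pelvis", "left_hip"), c("left_hip", "left_knee"),
    c("left_knee", "left_ankle"), c("left_ankle", "left_heel"),
    c("left_heel", "left_toe"),
    c("pelvis", "spine"), c("spine", "neck"), c("neck", "head"),
    c("head", "nose"),
    c("neck", "left_shoulder"), c("left_shoulder", "left_elbow"),
    c("left_elbow", "left_wrist"),
    c("neck", "right_shoulder"), c("right_shoulder", "right_elbow"),
    c("right_elbow", "right_wrist"))
  roles <- list(
    left_heel = "left_heel", right_heel = "right_heel",
    left_toe = "left_toe", right_toe = "right_toe",
    left_hip = "left_hip", right_hip = "right_hip",
    left_knee = "left_knee", right_knee = "right_knee",
    left_ankle = "left_ankle", right_ankle = "right_ankle",
    pelvis_root = "pelvis", trunk = "spine",
    head_top = "head", head_base = "nose")
  skeleton_definition("h36m21", kp, side, bones, roles)
}

#' @describeIn skeleton_definition Davis-protocol 22-marker set (marker-based
#'   systems). The Davis protocol has no heel markers; only the roles that map
#'   unambiguously are pre-bound, the rest are left to the user.
#' @export
skeleton_davis22 <- function() {
  bilateral <- c("acromion", "asis", "trochanter", "thigh_bar",
                 "femur_epicondyle", "fibula_head", "shank_bar",
                 "malleolus", "metatarsal1", "metatarsal5")
  kp <- c("c7", "sacrum",
          paste0("right_", bilateral), paste0("left_", bilateral))
  side <- c("center", "center", rep("right", 10), rep("left", 10))
  roles <- list(
    left_hip = "left_trochanter", right_hip = "right_trochanter",
    left_knee = "left_femur_epicondyle", right_knee = "right_femur_epicondyle",
    left_ankle = "left_malleolus", right_ankle = "right_malleolus",
    left_toe = "left_metatarsal1", right_toe = "right_metatarsal1",
    pelvis_root = "sacrum")
  skeleton_definition("davis22", kp, side, bones = NULL, roles = roles)
}

#' Look up a bundled skeleton by name
#'
#' @param x a `gait_skeleton`, or one of `"h36m21"`, `"davis22"`.
#' @return A `gait_skeleton`.
#' @export
as_skeleton <- function(x) {
  if (inherits(x, "gait_skeleton")) return(x)
  switch(as.character(x),
         h36m21 = skeleton_h36m21(),
         davis22 = skeleton_davis22(),
         stop("unknown skeleton '", x, "'"))
}

#' Resolve a gait role to a keypoint name
#'
#' @param skeleton a `gait_skeleton`.
#' @param role role name, e.g. `"left_heel"`.
#' @param required error (TRUE) or return NULL (FALSE) when unbound.
#' @return Keypoint name, or NULL.
#' @export
role_keypoint <- function(skeleton, role, required = TRUE) {
  kp <- skeleton$roles[[role]]
  if (is.null(kp) && required) {
    stop("skeleton '", skeleton$name, "' does not bind role '", role, "'")
  }
  kp
}
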