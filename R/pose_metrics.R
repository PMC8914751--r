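#' Percentage of Correct Keypoints, head-normalized (PCKh)
#'
#' A 2D estimate counts as correct when its Euclidean distance to the
#' ground truth is *strictly* below `tau` times the reference length (the
#' "head bone link"); ties count as incorrect. Missing samples (NA in
#' either input) are excluded from numerator and denominator. Reported
#' per keypoint and pooled; the pooled value is computed both over all
#' samples ("pooled") and as the mean of per-keypoint percentages
#' ("macro"), since conventions differ between papers.
#'
#' @param estimate,truth numeric arrays `frames x keypoints x 2` (pixels),
#'   matching shapes and keypoint order.
#' @param tau threshold multiplier(s), e.g. `c(0.5, 0.75, 1)`.
#' @param reference_length scalar or per-frame vector: the head-segment
#'   length in pixels. See [head_reference_length()].
#' @return data.frame with columns tau, keypoint (`"<all>"` for pooled
#'   rows), pckh_pct, n; attribute `"macro"` holds the mean-of-keypoints
#'   summary per tau.
#' @export
pckh <- function(estimate, truth, tau = c(0.5, 0.75, 1),
                 reference_length) {
  stopifnot(identical(dim(estimate), dim(truth)), dim(estimate)[3] == 2L)
  if (any(!is.finite(reference_length)) || any(reference_length <= 0)) {
    stop("reference_length must be positive")
  }
  nf <- dim(estimate)[1]
  K <- dim(estimate)[2]
  ref <- rep_len(reference_length, nf)
  kp <- dimnames(estimate)[[2]]
  if (is.null(kp)) kp <- paste0("kp", seq_len(K))
  d <- sqrt((estimate[, , 1] - truth[, , 1])^2 +
            (estimate[, , 2] - truth[, , 2])^2)
  d <- matrix(d, nf, K)
  valid <- is.finite(d)
  out <- list()
  macro <- numeric(0)
  for (tt in tau) {
    hit <- d < tt * ref          # strict inequality; recycled per column
    perkp <- vapply(seq_len(K), function(k) {
      v <- valid[, k]
      if (!any(v)) return(NA_real_)
      100 * sum(hit[v, k]) / sum(v)
    }, numeric(1))
    nk <- colSums(valid)
    out[[length(out) + 1L]] <- data.frame(
      tau = tt, keypoint = c(kp, "<all>"),
      pckh_pct = c(perkp, 100 * sum(hit[valid]) / sum(valid)),
      n = c(nk, sum(valid)))
    macro <- c(macro, mean(perkp, na.rm = TRUE))
  }
  res <- do.call(rbind, out)
  attr(res, "macro") <- stats::setNames(macro, paste0("tau", tau))
  res
}

#' Head-segment reference length from a 2D series
#'
#' The default PCKh reference: the per-record mean pixel distance between
#' the skeleton's designated head-segment endpoints (`head_top` and
#' `head_base` roles; `head` and `nose` in the bundled h36m21 skeleton).
#'
#' @param series a `kps2d` whose skeleton binds `head_top`/`head_base`.
#' @param per_frame return the per-frame lengths instead of their mean.
#' @return Scalar (or per-frame vector) length in pixels.
#' @export
head_reference_length <- function(series, per_frame = FALSE) {
  stopifnot(inherits(series, "kps2d"))
  top <- role_keypoint(series$skeleton, "head_top")
  base <- role_keypoint(series$skeleton, "head_base")
  a <- series$coords[, top, , drop = TRUE]
  b <- series$coords[, base, , drop = TRUE]
  if (is.null(dim(a))) { a <- matrix(a, 1); b <- matrix(b, 1) }
  len <- sqrt(rowSums((a - b)^2))
  if (per_frame) len else mean(len, na.rm = TRUE)
}

#' Mean Per Joint Position Error (MPJPE)
#'
#' Mean Euclidean distance in 3D between estimated and ground-truth
#' keypoints over all valid (frame, keypoint) pairs; the conventional
#' report unit is millimeters.
#'
#' @param estimate,truth numeric arrays `frames x keypoints x 3`, same
#'   units (meters in this package's containers).
#' @param per_keypoint also return the per-keypoint breakdown.
#' @return Scalar mean distance (input units); with `per_keypoint = TRUE`
#'   a list with `overall` and `per_keypoint`.
#' @export
mpjpe <- function(estimate, truth, per_keypoint = FALSE) {
  stopifnot(identical(dim(estimate), dim(truth)), dim(estimate)[3] == 3L)
  d <- sqrt((estimate[, , 1] - truth[, , 1])^2 +
            (estimate[, , 2] - truth[, , 2])^2 +
            (estimate[, , 3] - truth[, , 3])^2)
  d <- matrix(d, dim(estimate)[1], dim(estimate)[2])
  if (!any(is.finite(d))) stop("no valid (frame, keypoint) pairs")
  overall <- mean(d[is.finite(d)])
  if (!per_keypoint) return(overall)
  kp <- dimnames(estimate)[[2]]
  if (is.null(kp)) kp <- paste0("kp", seq_len(ncol(d)))
  pk <- vapply(seq_len(ncol(d)), function(k) {
    v <- is.finite(d[, k])
    if (!any(v)) NA_real_ else mean(d[v, k])
  }, numeric(1))
  list(overall = overall, per_keypoint = stats::setNames(pk, kp))
}
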