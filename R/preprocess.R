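#' Butterworth low-pass filter design
#'
#' Designs digital Butterworth low-pass coefficients by bilinear transform
#' of the analog prototype: analog poles on the Butterworth circle at the
#' prewarped cutoff, all zeros mapped to z = -1, numerator scaled for unit
#' DC gain. Returns transfer-function coefficients `b`, `a` (both length
#' `order + 1`, `a[1] = 1`).
#'
#' @param order filter order (>= 1).
#' @param cutoff_hz cutoff (-3 dB) frequency in Hz.
#' @param fs sampling rate in Hz; `cutoff_hz` must be below `fs / 2`.
#' @return List with numeric vectors `b` and `a`.
#' @export
butter_design <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, order == floor(order))
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie in (0, Nyquist); got ", cutoff_hz, " Hz at fs = ",
         fs, " Hz")
  }
  W <- cutoff_hz / (fs / 2)            # normalized, Nyquist = 1
  wa <- tan(pi * W / 2)                # prewarped analog cutoff (T = 2)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  pa <- wa * complex(real = cos(theta), imaginary = sin(theta))
  pz <- (1 + pa) / (1 - pa)            # bilinear transform
  a <- Re(poly_from_roots(pz))
  b <- choose(order, 0:order)          # zeros at z = -1: (1 + z^-1)^order
  b <- b * sum(a) / sum(b)             # exact unit DC gain
  list(b = as.numeric(b), a = as.numeric(a))
}

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# direct-form II transposed IIR filter with initial state zi
filter_df2t <- function(b, a, x, zi = NULL) {
  n <- length(a) - 1L
  z <- if (is.null(zi)) numeric(n) else zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1] * xm + z[1]
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        z[i] <- b[i + 1] * xm + z[i + 1] - a[i + 1] * ym
      }
    }
    z[n] <- b[n + 1] * xm - a[n + 1] * ym
    y[m] <- ym
  }
  y
}

# steady-state filter state for a unit step (Gustafsson-style startup)
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  comp <- matrix(0, n, n)              # companion matrix of a
  comp[1, ] <- -a[-1] / a[1]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(comp), B)
}

# zero-phase forward-backward filtering with odd-reflection padding
filtfilt_vec <- function(b, a, x) {
  padlen <- 3L * max(length(a), length(b))
  if (length(x) <= padlen) {
    stop("record too short for zero-phase filtering (need > ", padlen,
         " samples)")
  }
  ext <- c(2 * x[1] - x[(padlen + 1L):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1L):(length(x) - padlen)])
  zi <- lfilter_zi(b, a)
  y <- filter_df2t(b, a, ext, zi * ext[1])
  y <- rev(filter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + length(x))]
}

#' Zero-phase Butterworth low-pass filtering of trajectories
#'
#' Filters every keypoint and coordinate independently. The default is
#' zero-phase (forward-backward) application with odd-reflection padding,
#' the biomechanics norm: it introduces no group delay, so gait events keep
#' their timing. `order` is the order of the designed filter before the
#' forward-backward pass (so the two-pass magnitude response is the squared
#' single-pass response and the cutoff is the half-power point);
#' `order_convention = "effective"` instead designs order/2 so the combined
#' pass has the stated order.
#'
#' @param x a `kps3d`, `kps2d`, numeric matrix (frames x channels) or
#'   numeric vector.
#' @param cutoff_hz low-pass cutoff in Hz, below Nyquist. The gait pipeline
#'   uses 3 Hz for event detection and 12 Hz for kinematics.
#' @param order filter order, default 4.
#' @param fs sampling rate; taken from the series when `x` is one.
#' @param zero_phase apply forward-backward (default TRUE); FALSE gives a
#'   single causal pass.
#' @param order_convention `"design"` (default) or `"effective"` (see
#'   above; `"effective"` requires an even order).
#' @return Object of the same shape as `x`, filtered.
#' @export
butterworth_lowpass <- function(x, cutoff_hz, order = 4L, fs = NULL,
                                zero_phase = TRUE,
                                order_convention = c("design", "effective")) {
  order_convention <- match.arg(order_convention)
  if (order_convention == "effective") {
    if (!zero_phase) stop("'effective' convention only applies zero-phase")
    if (order %% 2L != 0L) stop("'effective' convention needs an even order")
    order <- order %/% 2L
  }
  if (inherits(x, "kps3d") || inherits(x, "kps2d")) {
    if (any(x$missing)) {
      stop("series has missing samples; run interpolate_gaps() first")
    }
    co <- x$coords
    des <- butter_design(order, cutoff_hz, x$fps)
    for (k in seq_len(dim(co)[2])) {
      for (d in seq_len(dim(co)[3])) {
        co[, k, d] <- apply_butter(des, co[, k, d], zero_phase)
      }
    }
    out <- x
    out$coords <- co
    return(out)
  }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  des <- butter_design(order, cutoff_hz, fs)
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- apply_butter(des, x[, j], zero_phase)
    x
  } else {
    apply_butter(des, as.numeric(x), zero_phase)
  }
}

apply_butter <- function(des, v, zero_phase) {
  if (anyNA(v)) stop("missing samples; run interpolate_gaps() first")
  if (zero_phase) filtfilt_vec(des$b, des$a, v)
  else filter_df2t(des$b, des$a, v)
}

#' Fill short occlusion gaps by cubic-spline interpolation
#'
#' Interior gaps of at most `max_gap_frames` missing samples are filled by a
#' natural cubic spline through the valid samples; longer gaps are left
#' missing and listed in the returned report; gaps touching the record edges
#' are held at the nearest valid value.
#'
#' @param series a `kps3d`.
#' @param max_gap_frames longest interior gap (in frames) that will be
#'   filled. Default 10.
#' @return The series with gaps filled; attribute `"gap_report"` is a
#'   data.frame of gaps left unfilled (keypoint, start_frame, end_frame,
#'   length).
#' @export
interpolate_gaps <- function(series, max_gap_frames = 10L) {
  stopifnot(inherits(series, "kps3d"))
  co <- series$coords
  n <- series$frames
  report <- list()
  for (k in seq_len(dim(co)[2])) {
    miss <- series$missing[, k]
    if (!any(miss)) next
    if (all(miss)) {
      stop("keypoint '", series$keypoints[k], "' is entirely missing")
    }
    valid <- which(!miss)
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      s <- starts[r]; e <- ends[r]; len <- e - s + 1L
      edge <- s == 1L || e == n
      if (edge) {
        hold <- if (s == 1L) min(valid) else max(valid)
        for (d in 1:3) co[s:e, k, d] <- co[hold, k, d]
      } else if (len <= max_gap_frames) {
        for (d in 1:3) {
          co[s:e, k, d] <- stats::spline(valid, co[valid, k, d],
                                         xout = s:e,
                                         method = "natural")$y
        }
      } else {
        report[[length(report) + 1L]] <-
          data.frame(keypoint = series$keypoints[k],
                     start_frame = s - 1L, end_frame = e - 1L, length = len)
      }
    }
  }
  out <- keypoint_series_3d(co, series$fps, keypoints = series$keypoints,
                            vertical_axis = series$vertical_axis,
                            skeleton = series$skeleton)
  attr(out, "gap_report") <- if (length(report)) do.call(rbind, report)
                             else data.frame(keypoint = character(),
                                             start_frame = integer(),
                                             end_frame = integer(),
                                             length = integer())
  out
}

#' Finite-difference velocity and speed of keypoint trajectories
#'
#' Central differences in the interior, one-sided differences at the record
#' edges, scaled by the sampling rate.
#'
#' @param x a `kps3d` (no missing samples), a numeric matrix
#'   (frames x dims), or a numeric vector.
#' @param fs sampling rate; taken from the series when `x` is one.
#' @return For a series: list with `velocity` (frames x keypoints x 3,
#'   m/s) and `speed` (frames x keypoints matrix of Euclidean magnitudes).
#'   For a matrix/vector: the differentiated object.
#' @export
velocity <- function(x, fs = NULL) {
  if (inherits(x, "kps3d")) {
    if (any(x$missing)) stop("missing samples; run interpolate_gaps() first")
    co <- x$coords
    vel <- array(NA_real_, dim(co), dimnames = dimnames(co))
    for (k in seq_len(dim(co)[2])) {
      vel[, k, ] <- diff_central(co[, k, , drop = TRUE], x$fps)
    }
    speed <- sqrt(apply(vel^2, c(1, 2), sum))
    return(list(velocity = vel, speed = speed))
  }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  if (is.matrix(x)) diff_central(x, fs) else drop(diff_central(cbind(x), fs))
}

diff_central <- function(m, fs) {
  if (is.null(dim(m))) m <- cbind(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  v <- matrix(NA_real_, n, ncol(m))
  v[1, ] <- (m[2, ] - m[1, ]) * fs
  v[n, ] <- (m[n, ] - m[n - 1, ]) * fs
  if (n > 2L) {
    v[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                       m[1:(n - 2), , drop = FALSE]) * (fs / 2)
  }
  v
}

#' Normalize a per-cycle curve to 101 samples (0-100% of the gait cycle)
#'
#' Linear interpolation onto 101 evenly spaced points; endpoints are
#' preserved exactly. This is the conventional grid for gait curves.
#'
#' @param curve numeric vector (>= 4 samples) or matrix (frames x channels).
#' @return Length-101 vector or `101 x channels` matrix.
#' @export
time_normalize <- function(curve) {
  if (is.matrix(curve)) {
    stopifnot(nrow(curve) >= 4L)
    return(apply(curve, 2, time_normalize))
  }
  stopifnot(length(curve) >= 4L, !anyNA(curve))
  n <- length(curve)
  if (n == 101L) return(curve)
  stats::approx(seq(0, 1, length.out = n), curve,
                xout = seq(0, 1, length.out = 101L))$y
}
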