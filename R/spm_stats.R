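#' Scalar paired t-test
#'
#' Two-sided paired t-test on subject-wise differences, df = n - 1. A zero
#' variance of the differences makes p undefined: the result is flagged
#' degenerate, with t = 0 when the mean difference is also zero and
#' t = +/-Inf otherwise (sign of the mean difference).
#'
#' @param a,b paired per-subject values, equal length n >= 3.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest_scalar <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s < .Machine$double.eps^0.75 * max(1, abs(m))) {
    t <- if (abs(m) < .Machine$double.eps) 0 else sign(m) * Inf
    return(list(t = t, df = n - 1L, p = NA_real_, mean_diff = m,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
       mean_diff = m, degenerate = FALSE)
}

# 1D EC density of a t field (Worsley); per unit resel
t_field_ec1 <- function(t, df) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + t^2 / df)^(-(df - 1) / 2)
}

# rft1d-style FWHM estimate from the residual field gradients
estimate_fwhm <- function(R) {
  ssq <- colSums(R^2)
  Q <- ncol(R)
  # central-difference gradient along nodes (one-sided at the edges)
  g <- t(apply(R, 1, function(r) {
    c(r[2] - r[1], (r[3:Q] - r[1:(Q - 2)]) / 2, r[Q] - r[Q - 1])
  }))
  v <- colSums(g^2) / (ssq + .Machine$double.eps)
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) return(Inf)
  rpn <- sqrt(v / (4 * log(2)))     # resels per node
  1 / mean(rpn)
}

#' One-dimensional (SPM) paired t-test over gait-cycle curves
#'
#' Computes the pointwise paired t statistic at each node of the
#' normalized cycle and a family-wise critical threshold `t*` at level
#' `alpha` (two-sided). With `method = "rft"` the threshold solves the
#' expected-Euler-characteristic equation for a smooth 1D t field whose
#' smoothness (FWHM) is estimated from the gradients of the normalized
#' residual curves; the threshold is clamped between the scalar-t and the
#' Bonferroni-over-nodes critical values (its exact small- and
#' large-smoothness limits). With `method = "permutation"` the threshold
#' is the (1 - alpha) quantile of the max-|t| distribution over sign
#' flips of the paired differences — exhaustive when `2^n <= 10000`,
#' otherwise Monte Carlo with `n_perm` draws (seeded).
#'
#' Suprathreshold clusters (maximal runs with `|t| > t*`) are reported
#' with approximate cluster-level p-values: under RFT from the expected
#' cluster count and an exponential cluster-extent distribution; under
#' permutation from the permutation distribution of the maximal cluster
#' extent at `t*`.
#'
#' @param curves_a,curves_b numeric matrices `subjects x nodes` (e.g.
#'   n x 101), paired by row.
#' @param alpha family-wise error level (default 0.05).
#' @param method `"rft"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutation count (default 10000).
#' @param seed seed for Monte-Carlo permutations (required there).
#' @return An `spm1d_result`: list with `t_curve`, `t_star`, `alpha`,
#'   `df`, `fwhm`, `resels`, `method`, `clusters` (data.frame:
#'   start_pct, end_pct, extent_nodes, extent_resels, max_t, p), and
#'   `reject_any`.
#' @export
paired_ttest_1d <- function(curves_a, curves_b, alpha = 0.05,
                            method = c("rft", "permutation"),
                            n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  curves_a <- as.matrix(curves_a)
  curves_b <- as.matrix(curves_b)
  stopifnot(identical(dim(curves_a), dim(curves_b)))
  n <- nrow(curves_a)
  Q <- ncol(curves_a)
  if (n < 3L) stop("need at least 3 paired subjects")
  D <- curves_a - curves_b
  m <- colMeans(D)
  s <- apply(D, 2, stats::sd)
  df <- n - 1L
  degenerate <- all(s < .Machine$double.eps^0.75)
  tcurve <- ifelse(s > 0, m / (s / sqrt(n)), 0)

  R <- sweep(D, 2, m)               # residuals
  fwhm <- estimate_fwhm(R / rep(pmax(s, .Machine$double.eps), each = n))
  resels <- (Q - 1) / fwhm

  t_scalar <- stats::qt(1 - alpha / 2, df)
  t_bonf <- stats::qt(1 - alpha / (2 * Q), df)

  perm_max_t <- NULL
  flips <- NULL
  if (method == "rft") {
    if (is.finite(fwhm)) {
      fwe <- function(t) {
        (1 - stats::pt(t, df)) + resels * t_field_ec1(t, df) - alpha / 2
      }
      t_star <- if (fwe(t_bonf) > 0) t_bonf
                else stats::uniroot(fwe, c(t_scalar * 0.5, t_bonf + 50),
                                    tol = 1e-10)$root
    } else t_star <- t_scalar
    t_star <- min(max(t_star, t_scalar), t_bonf)
  } else {
    exhaustive <- 2^n <= 10000
    if (exhaustive) {
      flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      if (is.null(seed)) stop("seed is required for Monte-Carlo permutation")
      flips <- with_sim_rng(seed, {
        matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      })
      flips[1, ] <- 1               # include the identity permutation
    }
    ssq <- colSums(D^2)
    mm <- (flips %*% D) / n          # P x Q permuted means
    vv <- sweep(-n * mm^2, 2, ssq, "+") / (n - 1)
    perm_tt <- abs(mm) / sqrt(pmax(vv, .Machine$double.eps) / n)
    perm_max_t <- apply(perm_tt, 1, max)
    t_star <- stats::quantile(perm_max_t, 1 - alpha, names = FALSE,
                              type = 1)
  }

  clusters <- find_clusters(tcurve, t_star, fwhm, Q)
  if (nrow(clusters)) {
    if (method == "rft" && is.finite(fwhm)) {
      Ec <- resels * t_field_ec1(t_star, df) + (1 - stats::pt(t_star, df))
      EN <- resels * (1 - stats::pt(t_star, df))
      beta <- if (EN > 0) Ec / EN else Inf
      clusters$p <- vapply(clusters$extent_resels, function(k) {
        min(1, 1 - exp(-Ec * exp(-beta * k)))
      }, numeric(1))
    } else if (method == "permutation") {
      perm_max_ext <- apply(perm_tt > t_star, 1, max_run_length)
      clusters$p <- vapply(clusters$extent_nodes, function(k) {
        max(mean(perm_max_ext >= k), 1 / nrow(perm_tt))
      }, numeric(1))
    } else {
      clusters$p <- NA_real_
    }
  }
  structure(list(t_curve = tcurve, t_star = t_star, alpha = alpha, df = df,
                 fwhm = fwhm, resels = resels, method = method,
                 clusters = clusters, reject_any = nrow(clusters) > 0L,
                 degenerate = degenerate),
            class = "spm1d_result")
}

find_clusters <- function(tcurve, t_star, fwhm, Q) {
  over <- abs(tcurve) > t_star
  out <- data.frame(start_pct = numeric(), end_pct = numeric(),
                    extent_nodes = integer(), extent_resels = numeric(),
                    max_t = numeric(), p = numeric())
  if (!any(over)) return(out)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    nodes <- starts[i]:ends[i]
    out <- rbind(out, data.frame(
      start_pct = 100 * (starts[i] - 1) / (Q - 1),
      end_pct = 100 * (ends[i] - 1) / (Q - 1),
      extent_nodes = length(nodes),
      extent_resels = length(nodes) / fwhm,
      max_t = max(abs(tcurve[nodes])),
      p = NA_real_))
  }
  out
}

max_run_length <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' @export
print.spm1d_result <- function(x, ...) {
  cat(sprintf("<spm1d_result> %s paired t-test: df = %d, FWHM = %.1f nodes, t* = %.3f (alpha %.2f)\n",
              x$method, x$df, x$fwhm, x$t_star, x$alpha))
  if (nrow(x$clusters)) {
    cat("  suprathreshold clusters:\n")
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("   %5.1f%%-%5.1f%% of cycle, max|t| = %.2f, p = %s\n",
                  cl$start_pct, cl$end_pct, cl$max_t,
                  formatC(cl$p, digits = 3)))
    }
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Marker vs markerless system comparison report
#'
#' Runs the full statistical comparison: scalar paired t-tests on
#' the six spatio-temporal parameters (deliberately without multiplicity
#' correction — the conservative choice for an agreement study, since
#' corrections would make differences harder to detect) and 1D SPM paired
#' t-tests on the five joint-angle curves.
#'
#' @param params_a,params_b data.frames paired by row (subjects), each
#'   with the six parameter columns stance_pct, swing_pct,
#'   stride_length_m, stride_width_m, stride_time_s, speed_m_s.
#' @param angles_a,angles_b named lists of `subjects x 101` matrices, one
#'   per angle name.
#' @param alpha family-wise level per test (default 0.05).
#' @param method 1D method: `"rft"` or `"permutation"`.
#' @param seed passed to [paired_ttest_1d()].
#' @return List of class `system_comparison`: `parameters` (data.frame:
#'   one row per parameter with means, t, df, p), `angles` (named list of
#'   `spm1d_result`), `cluster_table` (all suprathreshold clusters),
#'   `alpha`.
#' @export
compare_systems <- function(params_a, params_b, angles_a, angles_b,
                            alpha = 0.05, method = "rft", seed = NULL) {
  cols <- c("stance_pct", "swing_pct", "stride_length_m", "stride_width_m",
            "stride_time_s", "speed_m_s")
  stopifnot(all(cols %in% names(params_a)), all(cols %in% names(params_b)),
            nrow(params_a) == nrow(params_b))
  ptab <- do.call(rbind, lapply(cols, function(cc) {
    tst <- paired_ttest_scalar(params_a[[cc]], params_b[[cc]])
    data.frame(parameter = cc,
               mean_a = mean(params_a[[cc]]), sd_a = stats::sd(params_a[[cc]]),
               mean_b = mean(params_b[[cc]]), sd_b = stats::sd(params_b[[cc]]),
               t = tst$t, df = tst$df, p = tst$p,
               degenerate = tst$degenerate)
  }))
  stopifnot(identical(sort(names(angles_a)), sort(names(angles_b))))
  ares <- lapply(stats::setNames(nm = names(angles_a)), function(nm) {
    paired_ttest_1d(angles_a[[nm]], angles_b[[nm]], alpha = alpha,
                    method = method, seed = seed)
  })
  ctab <- do.call(rbind, lapply(names(ares), function(nm) {
    cl <- ares[[nm]]$clusters
    if (!nrow(cl)) return(NULL)
    cbind(data.frame(angle = nm), cl)
  }))
  if (is.null(ctab)) {
    ctab <- data.frame(angle = character(), start_pct = numeric(),
                       end_pct = numeric(), extent_nodes = integer(),
                       extent_resels = numeric(), max_t = numeric(),
                       p = numeric())
  }
  structure(list(parameters = ptab, angles = ares, cluster_table = ctab,
                 alpha = alpha, method = method),
            class = "system_comparison")
}

#' @export
print.system_comparison <- function(x, ...) {
  cat("<system_comparison> alpha =", x$alpha, ", 1D method =", x$method, "\n")
  print(x$parameters[, c("parameter", "mean_a", "mean_b", "t", "p")],
        digits = 4)
  cat("angle curves with suprathreshold clusters:",
      if (nrow(x$cluster_table)) "" else "none", "\n")
  if (nrow(x$cluster_table)) print(x$cluster_table, digits = 3)
  invisible(x)
}

#' Write a comparison report to disk (CSV + JSON)
#'
#' @param comparison a `system_comparison`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(comparison$parameters,
                   file.path(dir, "parameters_ttest.csv"), row.names = FALSE)
  utils::write.csv(comparison$cluster_table,
                   file.path(dir, "angle_clusters.csv"), row.names = FALSE)
  ang <- lapply(comparison$angles, function(a) {
    list(t_curve = a$t_curve, t_star = a$t_star, alpha = a$alpha,
         df = a$df, fwhm = a$fwhm, method = a$method,
         reject_any = a$reject_any, clusters = a$clusters)
  })
  jsonlite::write_json(ang, file.path(dir, "angle_spm.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
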