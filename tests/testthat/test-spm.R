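test_that("scalar paired t-test handles degenerate and exact cases", {
  a <- c(1, 2, 3, 4)
  res <- paired_ttest_scalar(a, a)
  expect_true(res$degenerate)
  expect_equal(res$t, 0)

  res2 <- paired_ttest_scalar(c(2, 0, 2, 0), c(1, 1, 1, 1))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  expect_false(res2$degenerate)

  res3 <- paired_ttest_scalar(c(2, 3, 4), c(1, 2, 3))
  expect_true(res3$degenerate)
  expect_equal(res3$t, Inf)
})

test_that("scalar test matches the closed-form computation", {
  set.seed(40)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- paired_ttest_scalar(a, b)
    d <- a - b
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_ref), n - 1)
    expect_equal(res$t, t_ref, tolerance = 1e-10)
    expect_equal(res$p, p_ref, tolerance = 1e-10)
    expect_equal(res$df, n - 1)
  }
})

test_that("RFT threshold sits between scalar-t and Bonferroni bounds", {
  set.seed(41)
  n <- 16; Q <- 101
  for (fwhm in c(5, 12, 25, 60)) {
    a <- smooth_null_curves(n, Q, fwhm)
    b <- smooth_null_curves(n, Q, fwhm)
    res <- paired_ttest_1d(a, b, method = "rft")
    t_scalar <- qt(1 - 0.05 / 2, n - 1)
    t_bonf <- qt(1 - 0.05 / (2 * Q), n - 1)
    expect_gte(res$t_star, t_scalar - 1e-12)
    expect_lte(res$t_star, t_bonf + 1e-12)
  }
})

test_that("smoothness limits recover scalar and Bonferroni thresholds", {
  set.seed(42)
  n <- 12; Q <- 101
  # infinitely smooth: every node identical
  base <- rnorm(n)
  a <- matrix(base, n, Q)
  b <- matrix(rnorm(n), n, Q)
  res <- paired_ttest_1d(a, b)
  expect_equal(res$t_star, qt(1 - 0.025, n - 1), tolerance = 1e-9)

  # white noise: rough field clamps at Bonferroni
  aw <- matrix(rnorm(n * Q), n, Q)
  bw <- matrix(rnorm(n * Q), n, Q)
  resw <- paired_ttest_1d(aw, bw)
  expect_equal(resw$t_star, qt(1 - 0.05 / (2 * Q), n - 1), tolerance = 1e-9)
})

test_that("null smooth fields rarely produce suprathreshold clusters", {
  set.seed(43)
  rejections <- vapply(1:200, function(r) {
    a <- smooth_null_curves(16, 101, 20)
    b <- smooth_null_curves(16, 101, 20)
    paired_ttest_1d(a, b, method = "rft")$reject_any
  }, logical(1))
  expect_lte(mean(rejections), 0.10)   # ~alpha = 0.05; allow MC slack
})

test_that("an injected late-swing offset is detected as an overlapping cluster", {
  set.seed(44)
  hits <- vapply(1:50, function(r) {
    a <- smooth_null_curves(16, 101, 20)
    b <- smooth_null_curves(16, 101, 20)
    b[, 71:81] <- b[, 71:81] + 3        # 3 residual SDs across 70-80%
    res <- paired_ttest_1d(a, b, method = "rft")
    nrow(res$clusters) > 0 &&
      any(res$clusters$start_pct <= 80 & res$clusters$end_pct >= 70)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permutation and RFT thresholds agree on smooth fields", {
  set.seed(45)
  ratio <- vapply(1:20, function(r) {
    a <- smooth_null_curves(16, 101, 20)
    b <- smooth_null_curves(16, 101, 20)
    trft <- paired_ttest_1d(a, b, method = "rft")$t_star
    tperm <- paired_ttest_1d(a, b, method = "permutation",
                             n_perm = 1000, seed = r)$t_star
    tperm / trft
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.10)
})

test_that("exhaustive sign-flip enumeration is used for small n", {
  set.seed(46)
  a <- matrix(rnorm(6 * 101), 6, 101)
  b <- matrix(rnorm(6 * 101), 6, 101)
  # 2^6 = 64 <= 10000: no seed needed, deterministic
  r1 <- paired_ttest_1d(a, b, method = "permutation")
  r2 <- paired_ttest_1d(a, b, method = "permutation")
  expect_identical(r1$t_star, r2$t_star)
  # Monte-Carlo path requires a seed
  aa <- matrix(rnorm(16 * 101), 16, 101)
  bb <- matrix(rnorm(16 * 101), 16, 101)
  expect_error(paired_ttest_1d(aa, bb, method = "permutation"), "seed")
})

test_that("cluster bookkeeping matches the t-curve", {
  set.seed(47)
  a <- smooth_null_curves(16, 101, 20)
  b <- smooth_null_curves(16, 101, 20)
  b[, 40:60] <- b[, 40:60] + 2.5
  res <- paired_ttest_1d(a, b)
  expect_true(res$reject_any == (nrow(res$clusters) > 0))
  for (i in seq_len(nrow(res$clusters))) {
    cl <- res$clusters[i, ]
    nodes <- (round(cl$start_pct) : round(cl$end_pct)) + 1
    expect_true(all(abs(res$t_curve[nodes]) > res$t_star))
    expect_gt(cl$p, 0); expect_lte(cl$p, 1)
  }
})

test_that("compare_systems produces the full 6 + 5 report", {
  set.seed(48)
  n <- 8
  mkparams <- function(jit) data.frame(
    stance_pct = 59 + rnorm(n, 0, jit), swing_pct = 41 + rnorm(n, 0, jit),
    stride_length_m = 1.35 + rnorm(n, 0, jit / 50),
    stride_width_m = 0.10 + rnorm(n, 0, jit / 100),
    stride_time_s = 1.13 + rnorm(n, 0, jit / 50),
    speed_m_s = 1.19 + rnorm(n, 0, jit / 20))
  angles <- function() {
    lapply(stats::setNames(nm = c("hip_flexion", "knee_flexion",
                                  "ankle_dorsiflexion", "hip_abduction",
                                  "pelvis_tilt")), function(nm) {
      smooth_null_curves(n, 101, 20)
    })
  }
  cmp <- compare_systems(mkparams(1), mkparams(1), angles(), angles(),
                         alpha = 0.05)
  expect_equal(nrow(cmp$parameters), 6L)
  expect_length(cmp$angles, 5L)

  # identical inputs: degenerate scalars, no clusters
  pa <- mkparams(1); aa <- angles()
  cmp2 <- compare_systems(pa, pa, aa, aa)
  expect_true(all(cmp2$parameters$degenerate))
  expect_equal(nrow(cmp2$cluster_table), 0L)

  d <- withr::local_tempdir()
  write_comparison(cmp, d)
  expect_true(file.exists(file.path(d, "parameters_ttest.csv")))
  expect_true(file.exists(file.path(d, "angle_spm.json")))
})
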