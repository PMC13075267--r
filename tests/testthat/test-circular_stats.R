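test_that("circular mean wraps correctly and flags the degenerate case", {
  cm <- circular_mean(c(10, 10, 10))
  expect_equal(cm$mean, 10)
  expect_equal(cm$rbar, 1)
  # wrap-around: 350 and 10 average to 0, not 180
  expect_equal(circular_mean(c(350, 10))$mean, 0, tolerance = 1e-9)
  # balanced angles: undefined mean
  deg <- circular_mean(c(0, 90, 180, 270))
  expect_false(deg$defined)
  expect_true(is.na(deg$mean))
})

test_that("circular SD recovers the generating dispersion of a wrapped normal", {
  expect_equal(circular_sd(rep(42, 10)), 0)
  withr::with_seed(31, {
    theta <- rnorm(1e4, mean = 70, sd = 10)
    expect_equal(circular_sd(theta), 10, tolerance = 0.5 / 10)
    # tight data: circular SD within 2% of the ordinary SD
    for (sigma in c(5, 10, 15)) {
      x <- rnorm(5000, sd = sigma)
      expect_equal(circular_sd(x), stats::sd(x), tolerance = 0.02)
    }
  })
  expect_warning(s <- circular_sd(c(0, 90, 180, 270)), "undefined")
  expect_true(is.infinite(s))
})

test_that("circular SD is invariant to constant rotations of the series", {
  withr::with_seed(32, theta <- rnorm(500, sd = 25))
  s0 <- circular_sd(theta)
  for (off in c(90, 360, -720, 133.7)) {
    expect_equal(circular_sd(theta + off), s0, tolerance = 1e-9)
  }
})

test_that("circular covariance has the small-angle limit and degenerate zeros", {
  # sine deviations shrink variances by a factor ~(1 - sigma^2), so the
  # small-angle limit needs tight dispersions
  withr::with_seed(33, {
    p <- rnorm(20000, sd = 5)
    r <- rnorm(20000, sd = 7)
    y <- rnorm(20000, sd = 6)
  })
  cov <- circular_covariance_matrix(p, r, y)
  expect_equal(cov, t(cov))
  # diagonals near the linear variances in rad^2, off-diagonals near 0
  expect_equal(diag(cov),
               c(pitch = stats::var(p), roll = stats::var(r),
                 yaw = stats::var(y)) * (pi / 180)^2,
               tolerance = 0.03)
  expect_lt(max(abs(cov[upper.tri(cov)])), 0.1 * min(diag(cov)))
  # constant axes give the zero matrix
  z <- circular_covariance_matrix(rep(1, 10), rep(2, 10), rep(3, 10))
  expect_equal(unname(z), matrix(0, 3, 3))
  # a duplicated axis makes the matrix singular
  dup <- circular_covariance_matrix(p, p, y)
  expect_lt(abs(det(dup)), 1e-12)
  # sine and linearized definitions agree for tight data
  lin <- circular_covariance_matrix(p, r, y, method = "linearized")
  expect_equal(cov, lin, tolerance = 0.02)
  # undefined mean propagates
  expect_warning(
    bad <- circular_covariance_matrix(c(0, 90, 180, 270), 1:4, 1:4),
    "undefined")
  expect_true(all(is.na(bad)))
})

test_that("generalized variance matches a cofactor-expansion oracle", {
  expect_equal(generalized_variance(matrix(0, 3, 3)), 0)
  expect_equal(generalized_variance(diag(c(2, 3, 4))), 24)
  det3_cofactor <- function(m) {
    m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
      m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
      m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  }
  withr::with_seed(34, {
    for (k in 1:25) {
      A <- matrix(rnorm(9), 3, 3)
      S <- crossprod(A)   # random PSD
      expect_equal(generalized_variance(S), det3_cofactor(S),
                   tolerance = 1e-12)
      # Hadamard's inequality
      expect_lte(generalized_variance(S), prod(diag(S)) + 1e-12)
    }
  })
  ns <- matrix(c(1, 2, 3, 2.1, 1, 0, 3, 0, 1), 3, 3)
  expect_error(generalized_variance(ns), "symmetric")
})

test_that("small-dispersion generalized variance approaches the variance product", {
  withr::with_seed(35, {
    p <- rnorm(50000, sd = 5); r <- rnorm(50000, sd = 5); y <- rnorm(50000, sd = 5)
  })
  gv <- generalized_variance(circular_covariance_matrix(p, r, y))
  target <- stats::var(p) * stats::var(r) * stats::var(y) * (pi / 180)^6
  expect_equal(gv, target, tolerance = 0.05)
})

test_that("window metrics recover ground-truth dispersions through the pipeline", {
  # a static infant: all metrics near zero
  static <- fuse_orientation(make_static_recording(10, 20, -30, duration = 60))
  m0 <- window_metrics(static)
  expect_lt(m0$pitch_csd, 0.5)
  expect_lt(m0$roll_csd, 0.5)
  expect_lt(m0$yaw_csd, 0.5)
  expect_lt(m0$gen_var, 1e-6)

  truth <- simulate_trajectory(duration = 300, seed = 36)
  o <- fuse_pipeline(truth)
  m <- window_metrics(o)
  expect_equal(m$n, 5900L)   # 6000 samples minus 5 s warm-up
  disp <- unname(truth$movement$dispersion)
  expect_equal(m$pitch_csd, disp[1], tolerance = 0.10)
  expect_equal(m$roll_csd, disp[2], tolerance = 0.10)
  expect_equal(m$yaw_csd, disp[3], tolerance = 0.10)
  expect_gt(m$gen_var, 0)
})

test_that("window metrics are circular: adding full turns changes nothing", {
  truth <- simulate_trajectory(duration = 60, seed = 37)
  o <- orient_from_truth(truth)
  m1 <- window_metrics(o)
  o2 <- o
  o2$roll <- o2$roll + 360
  o2$yaw <- o2$yaw - 720
  m2 <- window_metrics(o2)
  expect_equal(m2$pitch_csd, m1$pitch_csd, tolerance = 1e-9)
  expect_equal(m2$roll_csd, m1$roll_csd, tolerance = 1e-9)
  expect_equal(m2$yaw_csd, m1$yaw_csd, tolerance = 1e-9)
  expect_equal(m2$gen_var, m1$gen_var, tolerance = 1e-9)
})

test_that("window metrics respect windows, flags and accel-only contracts", {
  truth <- simulate_trajectory(duration = 120, seed = 38)
  o <- orient_from_truth(truth)
  m <- window_metrics(o, window = c(10, 70))
  expect_equal(m$n, 1200L)
  expect_error(window_metrics(o, window = c(-5, 60)), "within")
  expect_error(window_metrics(o, window = c(100, 40)), "within")
  # accel-only: yaw-dependent metrics are missing
  ao <- accel_only_orientation(render_imu(truth))
  ma <- window_metrics(ao)
  expect_true(is.na(ma$yaw_csd))
  expect_true(is.na(ma$gen_var))
  expect_false(is.na(ma$pitch_csd))
})
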