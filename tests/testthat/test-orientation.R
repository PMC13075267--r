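test_that("gravity-vector pitch/roll reproduces the canonical static poses", {
  flat <- pitch_roll_from_gravity(c(0, 0, 9.81))
  expect_equal(unname(flat), c(0, 0))
  # 45-degree rotation about the local y-axis: x picks up +9.81 sin(45),
  # and the pitch formula atan(-X / sqrt(Y^2 + Z^2)) gives -45
  pr45 <- pitch_roll_from_gravity(9.81 * c(sin(pi / 4), 0, cos(pi / 4)))
  expect_equal(unname(pr45[["pitch"]]), -45, tolerance = 1e-9)
  expect_equal(abs(pr45[["pitch"]]), 45, tolerance = 1e-9)
  expect_equal(unname(pr45[["roll"]]), 0)
  # 30-degree roll
  pr30 <- pitch_roll_from_gravity(c(0, 9.81 * sin(pi / 6), 9.81 * cos(pi / 6)))
  expect_equal(unname(pr30), c(0, 30), tolerance = 1e-9)
  # quadrant-aware roll covers inverted limbs
  pr120 <- pitch_roll_from_gravity(c(0, 9.81 * sin(2 * pi / 3),
                                     9.81 * cos(2 * pi / 3)))
  expect_equal(unname(pr120[["roll"]]), 120, tolerance = 1e-9)
  expect_error(pitch_roll_from_gravity(c(0, 0, 0)), "zero")
})

test_that("euler/quaternion conversions round-trip and preserve unit norm", {
  withr::with_seed(11, {
    for (k in 1:50) {
      yaw <- runif(1, -179, 179)
      pitch <- runif(1, -85, 85)
      roll <- runif(1, -179, 179)
      q <- quat_from_euler(yaw, pitch, roll)
      expect_equal(sum(q^2), 1, tolerance = 1e-12)
      e <- quat_to_euler(q)
      expect_equal(unname(e), c(yaw, pitch, roll), tolerance = 1e-6)
    }
  })
  # euler angles agree with the gravity formulas on static data
  q <- quat_from_euler(70, 20, -35)
  g <- 9.81 * drop(t(quat_to_matrix(q)) %*% c(0, 0, 1))
  pr <- pitch_roll_from_gravity(g)
  expect_equal(unname(pr), c(20, -35), tolerance = 1e-9)
})

test_that("fused pitch/roll/yaw matches gravity formula and heading on static poses", {
  withr::with_seed(12, {
    for (k in 1:20) {
      yaw <- runif(1, -170, 170)
      pitch <- runif(1, -70, 70)
      roll <- runif(1, -170, 170)
      rec <- make_static_recording(yaw, pitch, roll, duration = 15)
      o <- fuse_orientation(rec)
      use <- !o$flags$warmup
      g_pr <- pitch_roll_from_gravity(rec$accel[1, ])
      expect_lt(max(abs(o$pitch[use] - g_pr[["pitch"]])), 1)
      expect_lt(max(abs(babyimu:::wrap180(o$roll[use] - g_pr[["roll"]]))), 1)
      expect_lt(max(abs(babyimu:::wrap180(o$yaw[use] - yaw))), 1)
      expect_equal(sqrt(rowSums(o$quat^2)), rep(1, length(o$time)),
                   tolerance = 1e-9)
    }
  })
})

test_that("constant world-z rotation advances yaw at the gyro rate", {
  fs <- 20; n <- 1200
  t <- seq.int(0, n - 1) / fs
  quat <- babyimu:::euler_to_quat_matrix(10 * t, rep(0, n), rep(0, n))
  mag <- babyimu:::rotate_world_to_sensor(quat, c(cos(pi / 3), 0, -sin(pi / 3)))
  rec <- imu_recording(t, matrix(c(0, 0, 9.81), n, 3, byrow = TRUE),
                       matrix(c(0, 0, 10), n, 3, byrow = TRUE), mag, fs = fs)
  o <- fuse_orientation(rec)
  use <- which(!o$flags$warmup)
  yaw_unwrapped <- o$yaw[use[1]] +
    cumsum(c(0, babyimu:::wrap180(diff(o$yaw[use]))))
  rate <- unname(stats::coef(stats::lm(yaw_unwrapped ~ t[use]))[2])
  expect_equal(rate, 10, tolerance = 0.01)
  expect_lt(max(abs(o$pitch[use])), 1)
  expect_lt(max(abs(o$roll[use])), 1)
})

test_that("identity orientation stays at the identity quaternion", {
  rec <- make_static_recording(duration = 10)
  o <- fuse_orientation(rec)
  dev <- apply(o$quat, 1, function(q) quat_angle(q, c(1, 0, 0, 0)))
  expect_lt(max(dev), 0.5)
  expect_error(fuse_orientation(make_static_recording(duration = 4)),
               "warm-up")
})

test_that("accelerometer-only orientation is pitch/roll with yaw pinned to 0", {
  truth <- simulate_trajectory(duration = 60, seed = 13,
                               accel_sd = 0, gyro_sd = 0, mag_sd = 0,
                               movement_accel_sd = 0, gyro_bias = c(0, 0, 0))
  rec <- render_imu(truth)
  grav <- lowpass_gravity(rec)
  o <- accel_only_orientation(grav)
  expect_false(o$yaw_observable)
  expect_true(all(o$yaw == 0))
  pr <- pitch_roll_from_gravity(grav$g)
  expect_equal(o$pitch, pr[, "pitch"], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(o$roll, pr[, "roll"], tolerance = 1e-9, ignore_attr = TRUE)
  # a slow tumble with no linear acceleration: tracks the fused estimates
  fused <- fuse_orientation(rec)
  use <- !fused$flags$warmup
  expect_lt(max(abs(o$pitch[use] - fused$pitch[use])), 2)
  expect_lt(max(abs(babyimu:::wrap180(o$roll[use] - fused$roll[use]))), 2)
  # zero-magnitude samples are flagged invalid
  g2 <- grav; g2$g[5, ] <- 0
  o2 <- accel_only_orientation(g2)
  expect_true(o2$flags$invalid[5])
  expect_true(is.na(o2$pitch[5]))
})

test_that("axis_vector rotates sensor basis axes into the world frame", {
  o_id <- orient_from_euler(rep(0, 40), rep(0, 40), rep(0, 40))
  expect_equal(axis_vector(o_id, "y", t = 1), c(0, 1, 0), tolerance = 1e-12)
  o_yaw <- orient_from_euler(rep(90, 40), rep(0, 40), rep(0, 40))
  expect_equal(axis_vector(o_yaw, "x", t = 1), c(0, 1, 0), tolerance = 1e-9)
  # oracle: direct quaternion rotation, and always unit norm
  withr::with_seed(14, {
    for (k in 1:10) {
      e <- c(runif(1, -170, 170), runif(1, -80, 80), runif(1, -170, 170))
      o <- orient_from_euler(rep(e[1], 5), rep(e[2], 5), rep(e[3], 5))
      v <- axis_vector(o, "z", t = 0.1)
      expect_equal(v, quat_rotate(quat_from_euler(e[1], e[2], e[3]),
                                  c(0, 0, 1)), tolerance = 1e-9)
      expect_equal(sum(v^2), 1, tolerance = 1e-12)
    }
  })
  expect_error(axis_vector(o_id, "y", t = 5), "span")
})

test_that("fusion recovers a synthetic free-movement trajectory", {
  truth <- simulate_trajectory(duration = 300, seed = 15)
  o <- fuse_pipeline(truth)
  expect_lt(rms_orientation_error(o, truth), 2)
})
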