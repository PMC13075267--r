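# Builders for small in-memory fixtures used across the suite.

# A noise-free recording of a sensor held at a fixed orientation.
make_static_recording <- function(yaw = 0, pitch = 0, roll = 0,
                                  duration = 30, fs = 20,
                                  gyro_bias = c(0, 0, 0),
                                  mag_world = c(cos(pi / 3), 0, -sin(pi / 3))) {
  n <- round(duration * fs)
  t <- seq.int(0, n - 1) / fs
  q <- quat_from_euler(yaw, pitch, roll)
  Rt <- t(quat_to_matrix(q))
  acc <- matrix(9.81 * drop(Rt %*% c(0, 0, 1)), n, 3, byrow = TRUE)
  mag <- matrix(drop(Rt %*% mag_world), n, 3, byrow = TRUE)
  gyr <- matrix(gyro_bias, n, 3, byrow = TRUE)
  imu_recording(t, acc, gyr, mag, fs = fs)
}

# An orientation series taken directly from ground-truth quaternions,
# bypassing the fusion filter (for kinematics oracles).
orient_from_truth <- function(truth) {
  babyimu:::new_orientation_series(truth$time, truth$quat_true, truth$fs,
                                   mode = "fused")
}

# An orientation series from explicit Euler series (degrees).
orient_from_euler <- function(yaw, pitch, roll, fs = 20) {
  n <- length(pitch)
  quat <- babyimu:::euler_to_quat_matrix(yaw, pitch, roll)
  babyimu:::new_orientation_series(seq.int(0, n - 1) / fs, quat, fs,
                                   mode = "fused")
}

# Exact exponential-map quaternion integrator: the independent oracle for
# dead-reckoning gyroscope data (deg/s, one row per sample).
integrate_gyro <- function(q0, gyro, fs) {
  n <- nrow(gyro)
  q <- matrix(NA_real_, n, 4)
  q[1, ] <- q0
  for (i in 2:n) {
    w <- gyro[i, ] * pi / 180 / fs
    ang <- sqrt(sum(w^2))
    dq <- if (ang < 1e-15) c(1, 0, 0, 0) else c(cos(ang / 2), sin(ang / 2) * w / ang)
    q[i, ] <- quat_normalize(quat_multiply(q[i - 1, ], dq))
  }
  q
}

rms_orientation_error <- function(orient, truth, skip_warmup = TRUE) {
  use <- if (skip_warmup) which(!orient$flags$warmup) else seq_along(orient$time)
  e <- vapply(use, function(i) quat_angle(orient$quat[i, ], truth$quat_true[i, ]),
              numeric(1))
  sqrt(mean(e^2))
}

# Render + bias-correct + fuse: the standard estimation pipeline.
fuse_pipeline <- function(truth, params = fusion_params()) {
  rec <- render_imu(truth)
  rec <- correct_gyro(rec, suppressWarnings(estimate_gyro_bias(rec)))
  fuse_orientation(rec, params)
}
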