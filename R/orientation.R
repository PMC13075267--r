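#' Pitch and roll from the gravity vector
#'
#' A static sensor measures the surface-normal reaction to gravity: flat on a
#' table it reads `(0, 0, 9.81)` m/s^2; rotated 45 degrees about its local
#' y-axis it reads `(9.81 sin 45, 0, 9.81 cos 45)`.  Tilt follows directly
#' from the components `(X, Y, Z)` of that vector:
#' `pitch = atan(-X / sqrt(Y^2 + Z^2))` and `roll = atan2(Y, Z)`.
#' Roll uses the quadrant-aware arctangent so limb inversions
#' (`|roll| > 90` degrees) are representable; the values agree with the
#' scalar `atan(Y/Z)` throughout `(-90, 90)`.  Yaw — rotation about the
#' world vertical — leaves the gravity vector unchanged and is therefore
#' unobservable from the accelerometer alone.
#'
#' @param g Numeric length-3 gravity vector `(X, Y, Z)` in the sensor frame,
#'   m/s^2 (any nonzero magnitude), or an `n x 3` matrix of such vectors.
#' @return For a single vector, named numeric `c(pitch, roll)` in degrees
#'   (`pitch` in `(-90, 90)`, `roll` in `(-180, 180]`).  For a matrix, an
#'   `n x 2` matrix with columns `pitch`, `roll`.
#' @export
#' @examples
#' pitch_roll_from_gravity(c(0, 0, 9.81))
#' pitch_roll_from_gravity(9.81 * c(sin(pi / 4), 0, cos(pi / 4)))
pitch_roll_from_gravity <- function(g) {
  if (is.matrix(g)) {
    stopifnot(ncol(g) == 3)
    bad <- sqrt(rowSums(g^2)) == 0
    out <- cbind(
      pitch = atan2(-g[, 1], sqrt(g[, 2]^2 + g[, 3]^2)) * 180 / pi,
      roll = atan2(g[, 2], g[, 3]) * 180 / pi
    )
    out[bad, ] <- NA_real_
    return(out)
  }
  g <- as.numeric(g)
  stopifnot(length(g) == 3)
  if (sum(g^2) == 0)
    stop("zero gravity vector: orientation undefined")
  c(pitch = atan2(-g[1], sqrt(g[2]^2 + g[3]^2)) * 180 / pi,
    roll = atan2(g[2], g[3]) * 180 / pi)
}

#' Parameters of the orientation fusion filter
#'
#' @param beta Gradient-descent gain of the fusion filter (rad/s of
#'   correction authority).  Larger values trust the accelerometer and
#'   magnetometer more; smaller values trust the gyroscope.  Default 0.1.
#' @param warmup_s Seconds flagged as warm-up after initialization and
#'   excluded from downstream metrics. Default 5.
#' @param mag_reference Assumed world-frame magnetic field direction (unit
#'   vector, z up).  Only its existence matters to the filter — the earth
#'   field reference is re-derived from the measurements each step — but the
#'   synthetic renderer shares this default.  Default: dip 60 degrees below
#'   horizontal, `c(cos(pi/3), 0, -sin(pi/3))`.
#' @param accel_rejection The accelerometer only measures the gravity
#'   direction when the sensor is not accelerating, so correction steps are
#'   skipped (gyroscope-only propagation) whenever the measured magnitude
#'   deviates from 9.81 m/s^2 by more than this many m/s^2 — the standard
#'   validity gating of inertial-fusion practice.  Default 0.5; `Inf`
#'   disables the gate.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(beta = 0.1, warmup_s = 5,
                          mag_reference = c(cos(pi / 3), 0, -sin(pi / 3)),
                          accel_rejection = 0.5) {
  if (beta <= 0) stop("`beta` must be positive")
  if (warmup_s < 0) stop("`warmup_s` must be non-negative")
  if (accel_rejection <= 0) stop("`accel_rejection` must be positive")
  structure(list(beta = beta, warmup_s = warmup_s,
                 mag_reference = mag_reference / sqrt(sum(mag_reference^2)),
                 accel_rejection = accel_rejection),
            class = "fusion_params")
}

new_orientation_series <- function(time, quat, fs, mode,
                                   warmup = NULL, invalid = NULL,
                                   yaw_observable = TRUE) {
  n <- length(time)
  eul <- t(apply(quat, 1, quat_to_euler))
  pitch <- eul[, "pitch"]
  gimbal <- !is.na(pitch) & abs(pitch) > 89.9
  structure(
    list(
      time = time, quat = quat,
      pitch = pitch, roll = eul[, "roll"], yaw = eul[, "yaw"],
      fs = fs, mode = mode,
      flags = list(
        warmup = if (is.null(warmup)) logical(n) else warmup,
        gimbal = gimbal,
        invalid = if (is.null(invalid)) logical(n) else invalid
      ),
      yaw_observable = yaw_observable
    ),
    class = "orientation_series"
  )
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples @ %g Hz, mode %s%s\n",
              length(x$time), x$fs, x$mode,
              if (x$yaw_observable) "" else " (yaw unobservable, held at 0)"))
  cat(sprintf("  flagged: %d warmup, %d gimbal, %d invalid\n",
              sum(x$flags$warmup), sum(x$flags$gimbal), sum(x$flags$invalid)))
  invisible(x)
}

#' @export
length.orientation_series <- function(x) length(x$time)

# Heading (deg) of a magnetometer reading after removing the given tilt.
tilt_compensated_heading <- function(m, pitch, roll) {
  q_tilt <- quat_multiply(quat_from_euler(0, pitch, 0),
                          quat_from_euler(0, 0, roll))
  h <- quat_rotate(q_tilt, m)
  atan2(-h[2], h[1]) * 180 / pi
}

#' Estimate orientation by accelerometer/gyroscope/magnetometer fusion
#'
#' Gradient-descent sensor fusion in the style of Madgwick's AHRS filter:
#' the gyroscope propagates the orientation quaternion, and each step is
#' corrected (with authority `beta`) along the gradient of an error function
#' that aligns the predicted gravity direction with the normalized
#' accelerometer reading and the predicted earth magnetic field with the
#' normalized magnetometer reading.  The earth-field reference is rebuilt
#' from the current measurement each step, so only the field's dip (not its
#' declination) matters and yaw is a relative heading.
#'
#' The filter is initialized from the first sample (tilt from the
#' accelerometer, heading from the tilt-compensated magnetometer); the first
#' `warmup_s` seconds are flagged and excluded from downstream metrics.
#' Samples within 0.1 degree of the `|pitch| = 90` gimbal poles are flagged;
#' [window_metrics()] interpolates their yaw/roll from neighbors.
#'
#' @param rec An [imu_recording()]; the gyroscope should be bias-corrected
#'   with [correct_gyro()] first (residual bias is partly absorbed by the
#'   filter's error correction).  The accelerometer may be raw or the output
#'   of [lowpass_gravity()] substituted upstream.
#' @param params A [fusion_params()].
#' @return An `orientation_series`: per-sample sensor-to-world unit
#'   quaternion (`quat`, `n x 4` scalar-first), derived `pitch`, `roll`,
#'   `yaw` in degrees (intrinsic z-y-x convention), and sample flags.
#' @export
#' @examples
#' truth <- simulate_trajectory(duration = 30, seed = 2)
#' rec <- render_imu(truth)
#' rec <- correct_gyro(rec, estimate_gyro_bias(rec))
#' orient <- fuse_orientation(rec)
#' orient
fuse_orientation <- function(rec, params = fusion_params()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(params, "fusion_params"))
  n <- length(rec$time)
  if (n <= params$warmup_s * rec$fs)
    stop("recording shorter than the warm-up period")
  dt <- 1 / rec$fs
  beta <- params$beta
  quat <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("w", "x", "y", "z")))

  pr0 <- pitch_roll_from_gravity(rec$accel[1, ])
  m0 <- rec$mag[1, ]
  yaw0 <- if (sum(m0^2) > 0) {
    tilt_compensated_heading(m0 / sqrt(sum(m0^2)), pr0[1], pr0[2])
  } else 0
  q <- quat_from_euler(yaw0, pr0[1], pr0[2])
  quat[1, ] <- q

  for (i in 2:n) {
    # exact exponential-map gyro propagation (first-order integration loses
    # accuracy during vigorous movement at low sampling rates)
    omega <- rec$gyro[i, ] * pi / 180
    ang <- sqrt(sum(omega^2)) * dt
    q <- if (ang < 1e-12) q else {
      quat_multiply(q, c(cos(ang / 2), sin(ang / 2) * omega * dt / ang))
    }
    # gradient-descent correction, evaluated at the propagated state (the
    # accelerometer/magnetometer sample belongs to the post-step instant)
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    qdot <- c(0, 0, 0, 0)

    a <- rec$accel[i, ]
    na <- sqrt(sum(a^2))
    if (na > 0 && abs(na - 9.81) <= params$accel_rejection) {
      a <- a / na
      f <- c(2 * (x * z - w * y) - a[1],
             2 * (w * x + y * z) - a[2],
             1 - 2 * (x^2 + y^2) - a[3])
      J <- rbind(
        2 * c(-y, z, -w, x),
        2 * c(x, w, z, y),
        c(0, -4 * x, -4 * y, 0)
      )
      m <- rec$mag[i, ]
      nm <- sqrt(sum(m^2))
      if (nm > 0) {
        m <- m / nm
        h <- quat_rotate(q, m)          # measured field in the world frame
        bx <- sqrt(h[1]^2 + h[2]^2)     # earth-field reference: horizontal,
        bz <- h[3]                      # vertical components only
        fm <- c(
          bx * (1 - 2 * (y^2 + z^2)) + 2 * bz * (x * z - w * y) - m[1],
          2 * bx * (x * y - w * z) + 2 * bz * (w * x + y * z) - m[2],
          2 * bx * (x * z + w * y) + bz * (1 - 2 * (x^2 + y^2)) - m[3]
        )
        Jm <- rbind(
          c(-2 * bz * y, 2 * bz * z, -4 * bx * y - 2 * bz * w,
            -4 * bx * z + 2 * bz * x),
          c(-2 * bx * z + 2 * bz * x, 2 * bx * y + 2 * bz * w,
            2 * bx * x + 2 * bz * z, -2 * bx * w + 2 * bz * y),
          c(2 * bx * y, 2 * bx * z - 4 * bz * x,
            2 * bx * w - 4 * bz * y, 2 * bx * x)
        )
        f <- c(f, fm)
        J <- rbind(J, Jm)
      }
      s <- drop(crossprod(J, f))
      # saturated normalization: full gain beta for substantial error,
      # proportional below it -- a fixed-size normalized step would
      # limit-cycle ("chatter") around the exact solution
      ns <- sqrt(sum(s^2))
      if (ns > 0) qdot <- qdot - beta * s / max(ns, 0.05)
    }
    q <- quat_normalize(q + qdot * dt)
    quat[i, ] <- q
  }

  new_orientation_series(rec$time, quat, rec$fs, mode = "fused",
                         warmup = rec$time - rec$time[1] < params$warmup_s)
}

#' Orientation from the gravity vector alone (pitch/roll only)
#'
#' When only accelerometer data are available the information stream is
#' limited to pitch and roll; yaw cannot be computed from the gravity vector
#' (any rotation about the world vertical leaves it unchanged).  Yaw is set
#' to a constant 0 and the series is marked yaw-unobservable; quaternions are
#' built from pitch/roll only.  Samples with zero gravity magnitude are
#' flagged invalid and excluded downstream.
#'
#' @param grav A `gravity_series` from [lowpass_gravity()], or an
#'   [imu_recording()] (its accelerometer is used directly).
#' @param warmup_s Seconds flagged as warm-up for parity with
#'   [fuse_orientation()] output. Default 0 (this estimator has no memory).
#' @return An `orientation_series` with `mode = "accel_only"`.
#' @export
accel_only_orientation <- function(grav, warmup_s = 0) {
  if (inherits(grav, "imu_recording")) {
    g <- grav$accel; time <- grav$time; fs <- grav$fs
  } else if (inherits(grav, "gravity_series")) {
    g <- grav$g; time <- grav$time; fs <- grav$fs
  } else stop("`grav` must be a gravity_series or imu_recording")
  n <- length(time)
  invalid <- sqrt(rowSums(g^2)) == 0
  pr <- pitch_roll_from_gravity(g)
  quat <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("w", "x", "y", "z")))
  ok <- which(!invalid)
  for (i in ok) quat[i, ] <- quat_from_euler(0, pr[i, 1], pr[i, 2])
  quat[invalid, ] <- rep(c(1, 0, 0, 0), each = sum(invalid))
  out <- new_orientation_series(
    time, quat, fs, mode = "accel_only",
    warmup = time - time[1] < warmup_s,
    invalid = invalid, yaw_observable = FALSE
  )
  out$yaw <- numeric(n)   # exact 0: unobservable placeholder, not estimate
  out$pitch[invalid] <- NA_real_
  out$roll[invalid] <- NA_real_
  out$yaw[invalid] <- NA_real_
  out
}

#' World-frame direction of a sensor axis at a given time
#'
#' Rotates the chosen sensor basis axis into the world frame at the sample
#' nearest `t` — e.g. the direction the sensor's y-axis (along the limb
#' segment) points in the room.
#'
#' @param orient An `orientation_series`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param t Time, seconds; must lie within the series.
#' @return Unit length-3 numeric vector in the world frame.
#' @export
axis_vector <- function(orient, axis = c("x", "y", "z"), t) {
  stopifnot(inherits(orient, "orientation_series"))
  axis <- match.arg(axis)
  if (t < min(orient$time) - 1e-9 || t > max(orient$time) + 1e-9)
    stop("`t` outside the orientation series time span")
  i <- which.min(abs(orient$time - t))
  e <- c(x = 1, y = 2, z = 3)[[axis]]
  v <- c(0, 0, 0); v[e] <- 1
  quat_rotate(orient$quat[i, ], v)
}
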