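#' Synthetic infant-limb IMU data
#'
#' Ground-truth orientation trajectories emulate free infant leg movement as
#' recorded in 5-minute home segments: quiescent periods alternating with
#' movement bouts (Poisson onsets) during which the limb's pitch, roll and
#' yaw relax toward a smooth band-limited random target whose stationary
#' per-axis dispersion is configurable.  [render_imu()] inverts the
#' orientation model to produce raw sensor streams: the accelerometer reads
#' the world gravity vector rotated into the sensor frame plus band-limited
#' movement acceleration during bouts plus white noise; the gyroscope reads
#' the true sensor-frame angular velocity plus a constant bias plus white
#' noise; the magnetometer reads a fixed world reference field (dip 60
#' degrees below horizontal) rotated into the sensor frame plus white noise.
#'
#' All generators are pure functions of their arguments and `seed`.
#'
#' @name synth
NULL

# Vectorized z-y-x Euler (deg) -> n x 4 scalar-first quaternion matrix.
euler_to_quat_matrix <- function(yaw, pitch, roll) {
  hy <- yaw * pi / 360; hp <- pitch * pi / 360; hr <- roll * pi / 360
  cy <- cos(hy); sy <- sin(hy)
  cp <- cos(hp); sp <- sin(hp)
  cr <- cos(hr); sr <- sin(hr)
  cbind(
    w = cy * cp * cr + sy * sp * sr,
    x = cy * cp * sr - sy * sp * cr,
    y = cy * sp * cr + sy * cp * sr,
    z = sy * cp * cr - cy * sp * sr
  )
}

# Band-limited unit-variance Gaussian series (zero-phase Butterworth).
smooth_noise <- function(n, fs, band_hz, order = 2) {
  x <- stats::rnorm(n)
  if (band_hz < fs / 2) {
    bf <- signal::butter(order, band_hz / (fs / 2), type = "low")
    x <- filtfilt_zero_phase(bf$b, bf$a, x)
  }
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate a ground-truth limb-orientation trajectory
#'
#' @param duration Recording length, seconds. Default 300 (the standardized
#'   5-minute segment).
#' @param fs Sampling rate, Hz. Default 20.
#' @param bout_rate Movement-bout onsets per minute (Poisson). Default 4.
#' @param bout_duration_s Length of each bout, seconds. Default 5.
#' @param dispersion Length-3 target stationary dispersion of (pitch, roll,
#'   yaw), degrees. Default `c(15, 35, 35)`.
#' @param gyro_bias Constant gyroscope bias, deg/s.  The default magnitude
#'   (~0.02 deg/s per axis) matches the drift scale of a resting
#'   research-grade MEMS gyroscope: integrated uncorrected, about 6 degrees
#'   over 5 minutes.
#' @param accel_sd,gyro_sd,mag_sd White measurement-noise SDs: m/s^2, deg/s
#'   and normalized units respectively.
#' @param movement_accel_sd SD of movement-generated acceleration during
#'   bouts, m/s^2. Default 1.
#' @param movement_band_hz Bandwidth of movement acceleration, Hz.
#'   Default 6 (below the 8 Hz gravity-isolation cutoff).
#' @param angle_band_hz Bandwidth of the orientation target process, Hz.
#'   Default 0.2 (postural changes over a few seconds).
#' @param track_rate Relaxation rate toward the target during bouts, 1/s.
#'   Default 3 (fast enough that the limb reaches the target's stationary
#'   dispersion within a bout).
#' @param max_rate_dps Per-axis slew-rate cap on the angle trajectories,
#'   deg/s.  Default 120 (vigorous but physiological limb rotation).
#' @param mag_reference World magnetic field direction (unit vector).
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return A `synth_truth` list: `time`, `quat_true` (`n x 4`), Euler series
#'   `pitch`/`roll`/`yaw` (deg), `omega_true` (scalar geodesic rate, deg/s,
#'   length `n - 1`), `omega_sensor` (`n x 3` body rates, deg/s), `gate`
#'   (movement envelope in `[0, 1]`), and the noise/bias configuration.
#' @export
#' @examples
#' truth <- simulate_trajectory(duration = 20, seed = 1)
#' truth
simulate_trajectory <- function(duration = 300, fs = 20,
                                bout_rate = 4, bout_duration_s = 5,
                                dispersion = c(pitch = 15, roll = 35, yaw = 35),
                                gyro_bias = c(0.02, -0.015, 0.01),
                                accel_sd = 0.1, gyro_sd = 0.2, mag_sd = 0.01,
                                movement_accel_sd = 1,
                                movement_band_hz = 6,
                                angle_band_hz = 0.2, track_rate = 3,
                                max_rate_dps = 120,
                                mag_reference = c(cos(pi / 3), 0, -sin(pi / 3)),
                                seed = 1) {
  n <- round(duration * fs)
  if (n < 2) stop("duration * fs must be at least 2 samples")
  stopifnot(length(dispersion) == 3, all(dispersion >= 0),
            all(c(accel_sd, gyro_sd, mag_sd, movement_accel_sd) >= 0))
  time <- seq.int(0, n - 1) / fs
  dt <- 1 / fs

  withr::with_seed(seed, {
    # movement gate: Poisson bout onsets, smoothed indicator in [0, 1]
    n_bouts <- stats::rpois(1, bout_rate / 60 * duration)
    gate <- numeric(n)
    if (n_bouts > 0) {
      onsets <- sort(stats::runif(n_bouts, 0, max(0, duration - bout_duration_s)))
      for (on in onsets) {
        idx <- which(time >= on & time < on + bout_duration_s)
        gate[idx] <- 1
      }
      bf <- signal::butter(2, min(0.99, 1 / (fs / 2)), type = "low")
      gate <- pmin(1, pmax(0, filtfilt_zero_phase(bf$b, bf$a, gate)))
    }

    # per-axis angle trajectories: relax toward a band-limited target
    # during bouts, hold during quiescence
    # relax toward the target during bouts with a slew-rate cap (no infant
    # limb rotates at many hundreds of deg/s), hold during quiescence
    relax <- function(target) {
      th <- numeric(n)
      cap <- max_rate_dps * dt
      for (i in seq_len(n - 1)) {
        step <- dt * track_rate * gate[i] * (target[i] - th[i])
        th[i + 1] <- th[i] + min(cap, max(-cap, step))
      }
      th
    }
    angles <- matrix(0, n, 3, dimnames = list(NULL, c("pitch", "roll", "yaw")))
    for (a in 1:3) {
      target <- smooth_noise(n, fs, angle_band_hz) * dispersion[a]
      th <- relax(target)
      # calibrate the target amplitude so the realized circular SD of the
      # trajectory matches the configured dispersion (relaxation and finite
      # bouts otherwise attenuate it)
      if (dispersion[a] > 0 && stats::sd(th) > 1e-8) {
        scale <- 1
        for (it in 1:3) {
          s <- circular_sd(th)
          if (!is.finite(s) || s < 1e-8) break
          scale <- scale * dispersion[a] / s
          th <- relax(target * scale)
        }
      }
      angles[, a] <- th
    }

    quat <- euler_to_quat_matrix(angles[, "yaw"], angles[, "pitch"],
                                 angles[, "roll"])
    # body rates: sample i carries the mean rate over (t[i-1], t[i]], the
    # quantity a rate gyroscope integrated over the preceding sample interval
    # reports, so that stepwise integration reproduces quat exactly
    omega_sensor <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    for (i in seq.int(2, n)) {
      omega_sensor[i, ] <- quat_log_rate(quat[i - 1, ], quat[i, ]) * fs
    }
    omega_sensor[1, ] <- omega_sensor[2, ]
    d <- pmin(1, abs(rowSums(quat[-n, , drop = FALSE] * quat[-1, , drop = FALSE])))
    omega_true <- 2 * acos(d) * 180 / pi * fs

    structure(
      list(
        time = time, fs = fs, duration = duration,
        quat_true = quat,
        pitch = angles[, "pitch"], roll = angles[, "roll"],
        yaw = angles[, "yaw"],
        omega_true = omega_true, omega_sensor = omega_sensor,
        gate = gate,
        gyro_bias = as.numeric(gyro_bias),
        noise = list(accel_sd = accel_sd, gyro_sd = gyro_sd, mag_sd = mag_sd),
        movement = list(bout_rate = bout_rate,
                        bout_duration_s = bout_duration_s,
                        dispersion = dispersion,
                        movement_accel_sd = movement_accel_sd,
                        movement_band_hz = movement_band_hz),
        mag_reference = mag_reference / sqrt(sum(mag_reference^2)),
        seed = seed
      ),
      class = "synth_truth"
    )
  })
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(
    "<synth_truth> %.0f s @ %g Hz, %.0f%% in movement bouts, seed %d\n",
    x$duration, x$fs, 100 * mean(x$gate > 0.5), x$seed))
  cat(sprintf("  dispersion targets (deg): pitch %g, roll %g, yaw %g\n",
              x$movement$dispersion[1], x$movement$dispersion[2],
              x$movement$dispersion[3]))
  invisible(x)
}

# Rotate a fixed world vector into the sensor frame for every quaternion row.
rotate_world_to_sensor <- function(quat, v) {
  w <- quat[, 1]; x <- quat[, 2]; y <- quat[, 3]; z <- quat[, 4]
  cbind(
    (1 - 2 * (y^2 + z^2)) * v[1] + 2 * (x * y + w * z) * v[2] +
      2 * (x * z - w * y) * v[3],
    2 * (x * y - w * z) * v[1] + (1 - 2 * (x^2 + z^2)) * v[2] +
      2 * (y * z + w * x) * v[3],
    2 * (x * z + w * y) * v[1] + 2 * (y * z - w * x) * v[2] +
      (1 - 2 * (x^2 + y^2)) * v[3]
  )
}

#' Render a synthetic IMU recording from a ground-truth trajectory
#'
#' @param truth A `synth_truth` from [simulate_trajectory()].
#' @param meta Metadata list for the resulting recording (see
#'   [imu_recording()]).
#' @return An [imu_recording()] whose sensor streams are consistent with
#'   `truth` plus the configured bias and noise.
#' @export
render_imu <- function(truth, meta = list(child_id = "synthetic")) {
  stopifnot(inherits(truth, "synth_truth"))
  n <- length(truth$time)
  fs <- truth$fs
  withr::with_seed(truth$seed + 104729L, {
    grav <- rotate_world_to_sensor(truth$quat_true, c(0, 0, 9.81))
    move <- vapply(1:3, function(a) {
      smooth_noise(n, fs, truth$movement$movement_band_hz, order = 3) *
        truth$movement$movement_accel_sd * truth$gate
    }, numeric(n))
    accel <- grav + move +
      matrix(stats::rnorm(3 * n, sd = truth$noise$accel_sd), n, 3)
    gyro <- sweep(truth$omega_sensor, 2, -truth$gyro_bias) +
      matrix(stats::rnorm(3 * n, sd = truth$noise$gyro_sd), n, 3)
    mag <- rotate_world_to_sensor(truth$quat_true, truth$mag_reference) +
      matrix(stats::rnorm(3 * n, sd = truth$noise$mag_sd), n, 3)
    imu_recording(truth$time, accel, gyro, mag, fs = fs, meta = meta)
  })
}

#' Configuration for a simulated longitudinal cohort
#'
#' Defaults reflect a two-cohort infant study followed at 3, 6, 9 and 12
#' months: 31 increased-likelihood (ILA) and 17 low-likelihood (LLA)
#' children, variability metrics whose 3-month baselines and per-month
#' slopes match the scales observed in infant ankle recordings (pitch
#' circular SD growing ~0.7 deg/month, roll ~3.6, yaw ~4.2, generalized
#' variance ~0.06/month), Gaussian child-level and visit-level noise, and a
#' gross-motor score generated as a monotone (linear) function of each
#' visit's generalized variance plus noise.
#'
#' @param n_children Named integer vector, children per cohort.
#' @param ages Visit ages, months.
#' @param baseline Named metric means at the first age.
#' @param slope Named per-month metric slopes.
#' @param between_sd Named between-child (random-intercept) SDs.
#' @param resid_sd Named visit-level residual SDs.
#' @param msel_base,msel_age_slope Gross-motor raw-score intercept and
#'   per-month growth.
#' @param msel_link Score points added per SD of a visit's generalized
#'   variance above its age expectation (0 = score independent of the
#'   metrics).
#' @param msel_resid Residual SD of the score.
#' @param seed Integer RNG seed.
#' @return A list of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(
    n_children = c(ILA = 31, LLA = 17),
    ages = c(3, 6, 9, 12),
    baseline = c(pitch_csd = 14.8, roll_csd = 21.4, yaw_csd = 24.3,
                 gen_var = 0.025),
    slope = c(pitch_csd = 0.71, roll_csd = 3.63, yaw_csd = 4.17,
              gen_var = 0.06),
    between_sd = c(pitch_csd = 3, roll_csd = 5, yaw_csd = 5,
                   gen_var = 0.004),
    resid_sd = c(pitch_csd = 4.5, roll_csd = 8, yaw_csd = 8,
                 gen_var = 0.008),
    msel_base = 3, msel_age_slope = 1.7,
    msel_link = 1.5, msel_resid = 2.5,
    seed = 1) {
  stopifnot(all(n_children >= 2), all(between_sd >= 0), all(resid_sd >= 0))
  metrics <- c("pitch_csd", "roll_csd", "yaw_csd", "gen_var")
  for (v in list(baseline, slope, between_sd, resid_sd))
    stopifnot(all(metrics %in% names(v)))
  structure(
    list(n_children = n_children, ages = ages, baseline = baseline,
         slope = slope, between_sd = between_sd, resid_sd = resid_sd,
         msel_base = msel_base, msel_age_slope = msel_age_slope,
         msel_link = msel_link, msel_resid = msel_resid, seed = seed),
    class = "synth_cohort_config"
  )
}

#' Simulate a longitudinal cohort table of variability metrics
#'
#' One row per child-visit: per-child Gaussian random intercepts, linear age
#' effects per metric, visit-level residual noise, and a gross-motor raw
#' score linked monotonically to the visit's generalized variance (set
#' `msel_link = 0` for an independent score).  Circular SDs and the
#' generalized variance are truncated at zero (the configured noise scales
#' make truncation rare).  All simulated infants are non-walking.
#'
#' @param cfg A [synth_cohort_config()].
#' @return A `data.frame` (class `cohort_table`) with columns `child_id`,
#'   `cohort`, `age_months`, `pitch_csd`, `roll_csd`, `yaw_csd`, `gen_var`,
#'   `msel_gm`, `walking`.
#' @export
#' @examples
#' tab <- simulate_cohort(synth_cohort_config(seed = 7))
#' head(tab)
simulate_cohort <- function(cfg = synth_cohort_config()) {
  stopifnot(inherits(cfg, "synth_cohort_config"))
  metrics <- c("pitch_csd", "roll_csd", "yaw_csd", "gen_var")
  withr::with_seed(cfg$seed, {
    rows <- list()
    for (coh in names(cfg$n_children)) {
      nk <- cfg$n_children[[coh]]
      for (k in seq_len(nk)) {
        id <- sprintf("%s%03d", coh, k)
        b <- stats::rnorm(length(metrics), 0, cfg$between_sd[metrics])
        names(b) <- metrics
        for (age in cfg$ages) {
          mu <- cfg$baseline[metrics] + cfg$slope[metrics] * (age - cfg$ages[1])
          val <- mu + b + stats::rnorm(length(metrics), 0,
                                       cfg$resid_sd[metrics])
          val <- pmax(val, 0)
          z <- (val[["gen_var"]] - mu[["gen_var"]]) /
            sqrt(cfg$between_sd[["gen_var"]]^2 + cfg$resid_sd[["gen_var"]]^2)
          msel <- cfg$msel_base + cfg$msel_age_slope * age +
            cfg$msel_link * z + stats::rnorm(1, 0, cfg$msel_resid)
          rows[[length(rows) + 1L]] <- data.frame(
            child_id = id, cohort = coh, age_months = age,
            pitch_csd = val[["pitch_csd"]], roll_csd = val[["roll_csd"]],
            yaw_csd = val[["yaw_csd"]], gen_var = val[["gen_var"]],
            msel_gm = round(max(msel, 0), 1), walking = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
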