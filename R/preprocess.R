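#' Gravity isolation and gyroscope bias correction
#'
#' Movement-generated acceleration in infant recordings is transient and
#' concentrated at higher frequencies than the slowly varying gravitational
#' component, so a low-pass Butterworth filter separates the two.  The
#' default cutoff is 8 Hz, which at the 20 Hz sampling rate of the target
#' sensors leaves a narrow transition band up against the 10 Hz Nyquist
#' frequency; residual movement transients that pass the filter are further
#' attenuated downstream by the fusion filter's accelerometer weighting.
#'
#' @name preprocess
NULL

# ---- zero-phase IIR filtering ------------------------------------------------

# Steady-state initial conditions for the direct-form-II-transposed filter,
# scaled by the first input sample, so a constant input produces a constant
# output from sample one (DC gain exactly sum(b)/sum(a) = 1 for Butterworth).
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, numeric(nf - length(a)))
  b <- c(b, numeric(nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (nf == 1) return(numeric(0))
  # companion matrix of a, transposed
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[-1]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  IminusA <- diag(nf - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# Direct-form-II-transposed IIR filter with initial state zi.
iir_filter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  a <- c(a, numeric(nf - length(a)))
  b <- c(b, numeric(nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  n <- length(x)
  y <- numeric(n)
  z <- if (is.null(zi)) numeric(nf - 1) else zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2) {
      for (k in seq_len(nf - 2)) z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    }
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# Forward-backward filtering with odd-reflection edge padding and
# steady-state initial conditions: zero phase, no start-up transient.
filtfilt_zero_phase <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  pad <- min(n - 1L, 3L * (nf - 1L))
  if (pad > 0) {
    head_ext <- 2 * x[1] - x[(pad + 1):2]
    tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
    ext <- c(head_ext, x, tail_ext)
  } else {
    ext <- x
  }
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Isolate the gravitational component of acceleration
#'
#' Applies an order-`order` low-pass Butterworth filter forward and backward
#' (zero phase, unit DC gain) to each accelerometer axis.  The result is the
#' sensor-frame surface-normal ("gravity") vector series: for a static sensor
#' it equals the raw accelerometer reading, with magnitude 9.81 m/s^2.
#'
#' @param rec An [imu_recording()].
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist
#'   frequency `fs/2`.  Default 8 Hz.
#' @param order Butterworth order (of each pass). Default 4.
#' @return A `gravity_series`: list with `time`, `g` (`n x 3`, m/s^2), `fs`.
#' @export
#' @examples
#' rec <- render_imu(simulate_trajectory(duration = 10, seed = 1))
#' grav <- lowpass_gravity(rec)
#' summary(sqrt(rowSums(grav$g^2)))
lowpass_gravity <- function(rec, cutoff_hz = 8, order = 4) {
  stopifnot(inherits(rec, "imu_recording"))
  if (cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2)
    stop("`cutoff_hz` must lie in (0, fs/2) = (0, ", rec$fs / 2, ")")
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "low")
  g <- apply(rec$accel, 2, function(col) filtfilt_zero_phase(bf$b, bf$a, col))
  colnames(g) <- c("x", "y", "z")
  structure(list(time = rec$time, g = g, fs = rec$fs),
            class = "gravity_series")
}

#' @export
print.gravity_series <- function(x, ...) {
  cat(sprintf("<gravity_series> %d samples @ %g Hz, |g| in [%.3f, %.3f] m/s^2\n",
              length(x$time), x$fs,
              min(sqrt(rowSums(x$g^2))), max(sqrt(rowSums(x$g^2)))))
  invisible(x)
}

#' Estimate constant gyroscope bias from quiescent periods
#'
#' MEMS gyroscopes carry a slowly varying zero-rate offset that, integrated,
#' accumulates into orientation drift (an offset of 0.02 deg/s drifts 6
#' degrees over a 5-minute window).  This estimator detects quiescent runs —
#' gyroscope magnitude below `quiescence_threshold` sustained for at least
#' `min_quiescence_s` — and tracks the bias with a per-sample exponential
#' moving average over those runs.  On noise-free static data the estimate is
#' exact to numerical precision.
#'
#' @param rec An [imu_recording()].
#' @param quiescence_threshold Gyro magnitude below which a sample counts as
#'   quiescent, deg/s. Default 3.
#' @param min_quiescence_s Minimum sustained quiescence, seconds. Default 2.
#' @param ema_alpha Exponential-moving-average coefficient per sample.
#'   Default 0.02.
#' @return A `gyro_bias`: list with `bias` (length-3, deg/s) and
#'   `n_quiescent_samples`.  If no quiescent run is found the bias is zero,
#'   `n_quiescent_samples` is 0, and a warning is raised.
#' @seealso [correct_gyro()]
#' @export
estimate_gyro_bias <- function(rec, quiescence_threshold = 3,
                               min_quiescence_s = 2, ema_alpha = 0.02) {
  stopifnot(inherits(rec, "imu_recording"))
  if (quiescence_threshold <= 0) stop("`quiescence_threshold` must be positive")
  if (ema_alpha <= 0 || ema_alpha > 1) stop("`ema_alpha` must be in (0, 1]")
  n <- length(rec$time)
  min_run <- max(2L, round(min_quiescence_s * rec$fs))
  if (n < min_run) stop("recording shorter than `min_quiescence_s`")
  quiet <- sqrt(rowSums(rec$gyro^2)) < quiescence_threshold
  runs <- rle(quiet)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  idx <- unlist(mapply(seq.int, starts[keep], ends[keep], SIMPLIFY = FALSE))
  if (!length(idx)) {
    warning("no quiescent period found; returning zero bias")
    return(structure(list(bias = c(x = 0, y = 0, z = 0),
                          n_quiescent_samples = 0L),
                     class = "gyro_bias"))
  }
  bias <- rec$gyro[idx[1], ]
  for (i in idx[-1]) bias <- bias + ema_alpha * (rec$gyro[i, ] - bias)
  structure(list(bias = stats::setNames(as.numeric(bias), c("x", "y", "z")),
                 n_quiescent_samples = length(idx)),
            class = "gyro_bias")
}

#' @export
print.gyro_bias <- function(x, ...) {
  cat(sprintf("<gyro_bias> (%.4g, %.4g, %.4g) deg/s from %d quiescent samples\n",
              x$bias[1], x$bias[2], x$bias[3], x$n_quiescent_samples))
  invisible(x)
}

#' Subtract an estimated bias from the gyroscope channels
#'
#' @param rec An [imu_recording()].
#' @param bias A `gyro_bias` from [estimate_gyro_bias()], or a length-3
#'   numeric vector in deg/s.
#' @return The recording with bias-corrected gyroscope; other channels
#'   untouched.
#' @export
correct_gyro <- function(rec, bias) {
  stopifnot(inherits(rec, "imu_recording"))
  b <- if (inherits(bias, "gyro_bias")) bias$bias else bias
  stopifnot(length(b) == 3)
  rec$gyro <- sweep(rec$gyro, 2, as.numeric(b))
  rec
}
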