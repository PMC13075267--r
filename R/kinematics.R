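#' Composite angular velocity
#'
#' A scalar time series summarising how fast the limb's orientation is
#' changing, computed in two modes: the full-3D mode uses the fused
#' quaternion series and measures the geodesic angle between consecutive
#' orientations per unit time (which combines pitch, roll and yaw rates and
#' reduces to the plain rate on single-axis motion); the accelerometer-only
#' mode is the root-sum-square of the pitch and roll finite-difference
#' rates, the best available when no gyroscope/magnetometer is present.
#' Yaw motion is invisible to the accelerometer-only mode, which is
#' therefore a coarse lower-bound style estimate.
#'
#' @name kinematics
NULL

new_angular_velocity <- function(time, omega, mode) {
  structure(list(time = time, omega = omega, mode = mode),
            class = "angular_velocity_series")
}

#' @export
print.angular_velocity_series <- function(x, ...) {
  cat(sprintf(
    "<angular_velocity_series> %d samples, mode %s, mean %.2f deg/s\n",
    length(x$omega), x$mode, mean(x$omega, na.rm = TRUE)))
  invisible(x)
}

#' Full-3D composite angular velocity from fused orientation
#'
#' Default (`method = "geodesic"`):
#' `omega_i = 2 * acos(|<q_i, q_{i+1}>|) * (180/pi) * fs` — the geodesic
#' rotation angle between consecutive unit quaternions per unit time, in
#' deg/s.  This composite is parameterization-free and reduces exactly to
#' the plain rate on single-axis motion.  `method = "euler_rates"` instead
#' takes the root-sum-square of the three wrapped Euler-angle
#' finite-difference rates; the two agree on single-axis and small
#' simultaneous motion and differ at large combined excursions.
#'
#' Requires a fused orientation series: with accelerometer-only input the
#' yaw component of the rotation is unobservable and the full-3D rate is
#' undefined (use [angular_velocity_accel_only()]).
#'
#' @param orient An `orientation_series` with `mode = "fused"`.
#' @param method `"geodesic"` (default) or `"euler_rates"`.
#' @return An `angular_velocity_series` (length `n - 1`, timestamps at
#'   sample-pair midpoints, `mode = "full3d"`).
#' @export
angular_velocity_full <- function(orient,
                                  method = c("geodesic", "euler_rates")) {
  stopifnot(inherits(orient, "orientation_series"))
  method <- match.arg(method)
  if (orient$mode != "fused" || !orient$yaw_observable)
    stop("full-3D angular velocity needs fused orientation; ",
         "yaw is unobservable in accel-only mode")
  n <- length(orient$time)
  omega <- if (method == "geodesic") {
    q <- orient$quat
    d <- abs(rowSums(q[-n, , drop = FALSE] * q[-1, , drop = FALSE]))
    2 * acos(pmin(d, 1)) * 180 / pi * orient$fs
  } else {
    sqrt(wrap180(diff(orient$yaw))^2 + wrap180(diff(orient$pitch))^2 +
           wrap180(diff(orient$roll))^2) * orient$fs
  }
  new_angular_velocity((orient$time[-n] + orient$time[-1]) / 2, omega,
                       mode = "full3d")
}

wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Accelerometer-only composite angular velocity
#'
#' `omega_i = sqrt((dpitch_i * fs)^2 + (droll_i * fs)^2)` with angle
#' differences wrapped to `(-180, 180]` degrees.  Pure yaw rotation yields 0
#' by construction.
#'
#' @param orient An `orientation_series` (either mode; only pitch and roll
#'   are used).
#' @return An `angular_velocity_series` (`mode = "accel_only"`).
#' @export
angular_velocity_accel_only <- function(orient) {
  stopifnot(inherits(orient, "orientation_series"))
  n <- length(orient$time)
  dp <- wrap180(diff(orient$pitch))
  dr <- wrap180(diff(orient$roll))
  omega <- sqrt((dp * orient$fs)^2 + (dr * orient$fs)^2)
  new_angular_velocity((orient$time[-n] + orient$time[-1]) / 2, omega,
                       mode = "accel_only")
}

#' Compare two angular-velocity series
#'
#' Pearson correlation and pairwise mean absolute difference (MAD) between
#' aligned scalar angular-velocity series — the agreement summary used to
#' judge how well the accelerometer-only estimate tracks the full-3D one.
#'
#' @param a,b `angular_velocity_series` of equal length with aligned
#'   timestamps.
#' @return List with `r` (Pearson correlation; `NA` with a warning if either
#'   series has zero variance), `mad` (mean absolute difference, deg/s) and
#'   `n`.
#' @export
compare_angular_velocity <- function(a, b) {
  stopifnot(inherits(a, "angular_velocity_series"),
            inherits(b, "angular_velocity_series"))
  if (length(a$omega) != length(b$omega))
    stop("series lengths differ: ", length(a$omega), " vs ", length(b$omega))
  if (max(abs(a$time - b$time)) > 1e-6)
    stop("series timestamps are not aligned")
  ok <- stats::complete.cases(a$omega, b$omega)
  x <- a$omega[ok]; y <- b$omega[ok]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance series: correlation undefined")
    NA_real_
  } else {
    stats::cor(x, y)
  }
  list(r = r, mad = mean(abs(x - y)), n = sum(ok))
}
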