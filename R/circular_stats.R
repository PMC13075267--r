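#' Circular statistics for orientation angles
#'
#' Pitch, roll and yaw are circular variables: 359 degrees and 1 degree are
#' two degrees apart, not 358.  Dispersion summaries therefore use
#' circular-statistics definitions built on the mean resultant vector of the
#' angles mapped to the unit circle.
#'
#' @name circular_stats
NULL

#' Circular mean and resultant length
#'
#' The circular mean is `atan2(mean(sin), mean(cos))`; the mean resultant
#' length `rbar = |mean unit vector|` measures concentration (1 for
#' identical angles, 0 for angles balanced around the circle, where the mean
#' is undefined).
#'
#' @param theta Numeric vector of angles, degrees. `NA`s are dropped.
#' @return List with `mean` (degrees in `(-180, 180]`, `NA` when undefined),
#'   `rbar`, `n`, and `defined` (`FALSE` when `rbar < 1e-12`).
#' @export
#' @examples
#' circular_mean(c(350, 10))   # wraps to 0, not 180
circular_mean <- function(theta) {
  theta <- theta[!is.na(theta)]
  n <- length(theta)
  if (n < 1) stop("need at least one angle")
  rad <- theta * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  rbar <- sqrt(s^2 + c^2)
  defined <- rbar >= 1e-12
  list(mean = if (defined) atan2(s, c) * 180 / pi else NA_real_,
       rbar = rbar, n = n, defined = defined)
}

#' Circular standard deviation
#'
#' `sqrt(-2 * log(rbar))`, converted to degrees.  For a wrapped-normal
#' sample this recovers the generating sigma exactly in expectation, and for
#' tightly concentrated data it agrees with the ordinary standard deviation.
#' Returns `Inf` with a warning when the resultant length is numerically
#' zero (uniformly spread angles).
#'
#' @param theta Numeric vector of angles, degrees (`n >= 2` after dropping
#'   `NA`s).
#' @return Circular SD in degrees.
#' @export
circular_sd <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) < 2) stop("need at least two angles")
  cm <- circular_mean(theta)
  if (!cm$defined) {
    warning("zero resultant length: circular SD is undefined (infinite)")
    return(Inf)
  }
  sqrt(-2 * log(cm$rbar)) * 180 / pi
}

#' Circular covariance matrix of pitch, roll and yaw
#'
#' Entry `(j, k)` is `mean(sin(theta_j - mu_j) * sin(theta_k - mu_k))` with
#' `mu` the circular means and angles in radians — the sine-deviation
#' covariance of the circular-statistics literature (`method = "sine"`,
#' the default).  `method = "linearized"` instead takes the ordinary
#' (1/n-normalized) covariance of the deviations wrapped to
#' `(-180, 180]` degrees and converted to radians; the two agree in the
#' small-dispersion limit.  Either way the result is symmetric positive
#' semidefinite with entries in rad^2.
#'
#' @param pitch,roll,yaw Equal-length numeric angle vectors, degrees.
#' @param method `"sine"` (default) or `"linearized"`.
#' @return A symmetric 3x3 matrix (rad^2), or a matrix of `NA`s (with a
#'   warning) when any axis has an undefined circular mean.
#' @export
circular_covariance_matrix <- function(pitch, roll, yaw,
                                       method = c("sine", "linearized")) {
  method <- match.arg(method)
  series <- list(pitch = pitch, roll = roll, yaw = yaw)
  n <- unique(lengths(series))
  if (length(n) != 1) stop("pitch, roll and yaw must have equal length")
  ok <- stats::complete.cases(pitch, roll, yaw)
  if (sum(ok) < 2) stop("need at least two complete samples")
  series <- lapply(series, `[`, ok)
  mus <- lapply(series, circular_mean)
  out <- matrix(NA_real_, 3, 3,
                dimnames = list(names(series), names(series)))
  if (!all(vapply(mus, `[[`, TRUE, "defined"))) {
    warning("undefined circular mean on at least one axis; covariance is NA")
    return(out)
  }
  dev <- mapply(function(th, mu) {
    d <- wrap180(th - mu$mean) * pi / 180
    if (method == "sine") sin(d) else d
  }, series, mus)
  out[] <- crossprod(dev) / nrow(dev)
  out
}

#' Generalized variance: determinant of the circular covariance matrix
#'
#' Collapses multi-axis orientation variability to one non-negative scalar.
#' It is zero whenever any axis is constant or two axes are perfectly
#' collinear, and in the small-dispersion limit tends to the product of the
#' per-axis variances (rad^2).
#'
#' @param cov Symmetric positive-semidefinite 3x3 matrix, e.g. from
#'   [circular_covariance_matrix()].
#' @return The determinant; tiny negative values (above `-1e-12`) arising
#'   from round-off are clamped to 0.
#' @export
generalized_variance <- function(cov) {
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(dim(cov), c(3L, 3L)))) stop("`cov` must be 3x3")
  if (anyNA(cov)) return(NA_real_)
  if (max(abs(cov - t(cov))) > 1e-9)
    stop("`cov` is not symmetric within 1e-9")
  d <- det(cov)
  if (d < 0) {
    if (d < -1e-12)
      warning("determinant substantially negative (", format(d),
              "): input is not positive semidefinite; clamping to 0")
    d <- 0
  }
  d
}

# Replace values at flagged positions by circular interpolation from
# neighbors (via interpolated sine/cosine); used for gimbal-locked samples.
interp_angle <- function(time, theta, bad) {
  if (!any(bad) || all(bad)) return(theta)
  rad <- theta * pi / 180
  s <- stats::approx(time[!bad], sin(rad[!bad]), xout = time[bad],
                     rule = 2)$y
  c <- stats::approx(time[!bad], cos(rad[!bad]), xout = time[bad],
                     rule = 2)$y
  theta[bad] <- atan2(s, c) * 180 / pi
  theta
}

#' Orientation-variability metrics over a time window
#'
#' Computes the per-axis circular SDs (degrees) and the generalized variance
#' over `window`, excluding warm-up and invalid samples.  At gimbal-locked
#' samples yaw and roll are not separately identifiable, so their values are
#' interpolated from neighboring samples before the metrics are taken.
#' For accelerometer-only orientation the yaw series is a constant
#' placeholder, so `yaw_csd` and `gen_var` are `NA`.
#'
#' @param orient An `orientation_series`.
#' @param window Length-2 numeric, `c(start, end)` seconds (relative to the
#'   first sample); default spans the whole series.
#' @param cov_method Passed to [circular_covariance_matrix()].
#' @return A `variability_metrics` list: `pitch_csd`, `roll_csd`, `yaw_csd`
#'   (degrees), `gen_var`, `n` (valid samples used) and `window`.
#' @export
window_metrics <- function(orient, window = NULL,
                           cov_method = c("sine", "linearized")) {
  stopifnot(inherits(orient, "orientation_series"))
  cov_method <- match.arg(cov_method)
  t0 <- orient$time[1]
  span <- c(0, length(orient$time) / orient$fs)
  if (is.null(window)) window <- span
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9 ||
      window[2] <= window[1])
    stop("`window` must be an increasing pair within the series span")
  rel <- orient$time - t0
  # half-open [start, end): a [0, 300) window at 20 Hz uses 6000 samples
  inside <- rel >= window[1] - 1e-9 & rel < window[2] - 1e-9
  use <- inside & !orient$flags$warmup & !orient$flags$invalid
  if (sum(use) < 2)
    stop("fewer than 2 valid samples in the window")
  gim <- orient$flags$gimbal
  roll <- interp_angle(orient$time, orient$roll, gim & use)[use]
  yaw <- interp_angle(orient$time, orient$yaw, gim & use)[use]
  pitch <- orient$pitch[use]

  pitch_csd <- circular_sd(pitch)
  roll_csd <- circular_sd(roll)
  if (orient$yaw_observable) {
    yaw_csd <- circular_sd(yaw)
    cov <- suppressWarnings(
      circular_covariance_matrix(pitch, roll, yaw, method = cov_method))
    gen_var <- if (anyNA(cov)) NA_real_ else generalized_variance(cov)
  } else {
    yaw_csd <- NA_real_
    gen_var <- NA_real_
  }
  structure(
    list(pitch_csd = pitch_csd, roll_csd = roll_csd, yaw_csd = yaw_csd,
         gen_var = gen_var, n = sum(use), window = window),
    class = "variability_metrics"
  )
}

#' @export
print.variability_metrics <- function(x, ...) {
  cat(sprintf(
    "<variability_metrics> window [%g, %g] s, n = %d\n", x$window[1],
    x$window[2], x$n))
  cat(sprintf(
    "  circular SD (deg): pitch %.2f, roll %.2f, yaw %s\n",
    x$pitch_csd, x$roll_csd,
    if (is.na(x$yaw_csd)) "NA" else sprintf("%.2f", x$yaw_csd)))
  cat(sprintf("  generalized variance: %s\n",
              if (is.na(x$gen_var)) "NA" else format(x$gen_var, digits = 4)))
  invisible(x)
}
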