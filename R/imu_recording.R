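#' IMU recordings
#'
#' An `imu_recording` bundles synchronized tri-axial accelerometer, gyroscope
#' and magnetometer series with the sampling rate and visit metadata.
#' Canonical units are m/s^2 (accelerometer), deg/s (gyroscope) and
#' unit-normalized magnetometer readings; time is in seconds on a uniform
#' grid with step `1/fs`.
#'
#' @param time Numeric vector of sample times, seconds, uniformly spaced.
#' @param accel,gyro,mag Numeric `n x 3` matrices (columns x, y, z).
#' @param fs Sampling rate, Hz.
#' @param meta Named list of visit metadata: `child_id`, `side` ("left" or
#'   "right"), `age_months`, `cohort` ("ILA" or "LLA"), `walking` (logical).
#'   Missing entries are filled with defaults.
#' @return An object of class `imu_recording`.
#' @export
#' @examples
#' t <- seq(0, 0.45, by = 0.05)
#' g <- matrix(rep(c(0, 0, 9.81), each = 10), ncol = 3)
#' z <- matrix(0, 10, 3)
#' rec <- imu_recording(t, g, z, z, fs = 20)
#' rec
imu_recording <- function(time, accel, gyro, mag, fs,
                          meta = list()) {
  accel <- as_xyz_matrix(accel, "accel")
  gyro <- as_xyz_matrix(gyro, "gyro")
  mag <- as_xyz_matrix(mag, "mag")
  n <- length(time)
  if (n < 2) stop("an IMU recording needs at least 2 samples")
  if (nrow(accel) != n || nrow(gyro) != n || nrow(mag) != n)
    stop("accel, gyro and mag must all have one row per time sample")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  dt <- diff(time)
  if (any(abs(dt - 1 / fs) > 0.01 / fs))
    stop("non-uniform sampling: time steps deviate from 1/fs by more than 1%")
  bad <- which(!stats::complete.cases(cbind(time, accel, gyro, mag)))
  if (length(bad))
    stop("NaN/NA samples at rows: ", paste(utils::head(bad, 10), collapse = ", "))
  meta <- utils::modifyList(default_meta(), meta)
  structure(
    list(time = as.numeric(time), accel = accel, gyro = gyro, mag = mag,
         fs = fs, meta = meta),
    class = "imu_recording"
  )
}

default_meta <- function() {
  list(child_id = "unknown", side = "left", age_months = NA_real_,
       cohort = NA_character_, walking = FALSE)
}

as_xyz_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("`", what, "` must have 3 columns (x, y, z)")
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf(
    "<imu_recording> %d samples @ %g Hz (%.1f s)\n", n, x$fs, n / x$fs))
  cat(sprintf("  child %s, %s ankle, age %s mo, cohort %s, walking: %s\n",
              x$meta$child_id, x$meta$side,
              format(x$meta$age_months), format(x$meta$cohort),
              format(x$meta$walking)))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) length(x$time)

#' Column map and units of an on-disk IMU CSV
#'
#' The canonical on-disk layout is one row per sample with columns
#' `time_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z, mag_x, mag_y, mag_z`
#' and metadata (sampling rate, child id, ...) in a sidecar JSON next to the
#' CSV.  Vendor exports with other column names or units are declared through
#' a dialect: readings are converted to the canonical units (m/s^2, deg/s) on
#' read.
#'
#' @param time,accel,gyro,mag Column names: `time` a single name, the sensor
#'   arguments length-3 character vectors in x, y, z order.
#' @param accel_unit `"m/s2"` or `"g"` (1 g = 9.81 m/s^2).
#' @param gyro_unit `"deg/s"` or `"rad/s"`.
#' @param time_unit `"s"` or `"ms"`.
#' @return A list of class `imu_dialect`.
#' @export
imu_dialect <- function(time = "time_s",
                        accel = c("acc_x", "acc_y", "acc_z"),
                        gyro = c("gyr_x", "gyr_y", "gyr_z"),
                        mag = c("mag_x", "mag_y", "mag_z"),
                        accel_unit = c("m/s2", "g"),
                        gyro_unit = c("deg/s", "rad/s"),
                        time_unit = c("s", "ms")) {
  structure(
    list(time = time, accel = accel, gyro = gyro, mag = mag,
         accel_unit = match.arg(accel_unit),
         gyro_unit = match.arg(gyro_unit),
         time_unit = match.arg(time_unit)),
    class = "imu_dialect"
  )
}

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    sub("\\.csv$", ".json", path, ignore.case = TRUE)
  } else {
    paste0(path, ".json")
  }
}

#' Read an IMU recording from CSV (+ sidecar JSON metadata)
#'
#' @param path Path to the CSV file.  Metadata and sampling rate are read
#'   from the sidecar JSON (same path with extension `.json`) when present;
#'   otherwise `fs` is inferred from the time column and metadata defaults
#'   are used.
#' @param dialect An [imu_dialect()] describing column names and input units.
#' @return An [imu_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, dialect = imu_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  needed <- c(dialect$time, dialect$accel, dialect$gyro, dialect$mag)
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  time <- df[[dialect$time]]
  if (dialect$time_unit == "ms") time <- time / 1000
  accel <- as.matrix(df[dialect$accel])
  if (dialect$accel_unit == "g") accel <- accel * 9.81
  gyro <- as.matrix(df[dialect$gyro])
  if (dialect$gyro_unit == "rad/s") gyro <- gyro * 180 / pi
  mag <- as.matrix(df[dialect$mag])

  side <- sidecar_path(path)
  meta <- list(); fs <- NULL
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- sc$fs
    meta <- sc$meta
    if (is.null(meta)) meta <- list()
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(time))
  imu_recording(time, accel, gyro, mag, fs = fs, meta = meta)
}

#' Write an IMU recording to CSV (+ sidecar JSON metadata)
#'
#' Numeric fields survive a write/read round trip to better than 1e-9.
#'
#' @param rec An [imu_recording()].
#' @param path Output CSV path; the sidecar JSON is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(
    time_s = rec$time,
    acc_x = rec$accel[, 1], acc_y = rec$accel[, 2], acc_z = rec$accel[, 3],
    gyr_x = rec$gyro[, 1], gyr_y = rec$gyro[, 2], gyr_z = rec$gyro[, 3],
    mag_x = rec$mag[, 1], mag_y = rec$mag[, 2], mag_z = rec$mag[, 3]
  )
  df[] <- lapply(df, function(col) sprintf("%.12g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, meta = rec$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Extract a time window from a recording
#'
#' Cuts `duration * fs` samples starting `start` seconds after the first
#' sample.  A 5-minute window at 20 Hz yields 6000 samples.  Metadata and
#' original time stamps are preserved.
#'
#' @param rec An [imu_recording()].
#' @param start Window start, seconds relative to the first sample.
#' @param duration Window length, seconds.
#' @return An [imu_recording()] with `round(duration * fs)` samples.
#' @export
segment_window <- function(rec, start, duration) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$time)
  i0 <- round(start * rec$fs) + 1L
  len <- round(duration * rec$fs)
  if (i0 < 1L || len < 2L || i0 + len - 1L > n)
    stop(sprintf(
      "window [%g, %g] s out of range for a %.2f s recording",
      start, start + duration, n / rec$fs))
  idx <- seq.int(i0, i0 + len - 1L)
  imu_recording(rec$time[idx], rec$accel[idx, , drop = FALSE],
                rec$gyro[idx, , drop = FALSE], rec$mag[idx, , drop = FALSE],
                fs = rec$fs, meta = rec$meta)
}
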