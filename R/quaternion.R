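#' Quaternion utilities
#'
#' Unit quaternions are stored scalar-first as numeric vectors `c(w, x, y, z)`
#' (or row-wise in an `n x 4` matrix for series) and represent the
#' sensor-to-world rotation: a vector `v` expressed in the sensor frame maps
#' to the world frame as `q %q% v %q% q*`.
#'
#' The Euler-angle convention throughout the package is intrinsic z-y-x:
#' yaw about the world z-axis, then pitch about the intermediate y-axis, then
#' roll about the sensor x-axis.  On static data this reduces to the
#' gravity-vector formulas `pitch = atan2(-X, sqrt(Y^2 + Z^2))` and
#' `roll = atan2(Y, Z)` (see [pitch_roll_from_gravity()]).
#'
#' @param p,q Quaternions, scalar-first length-4 numeric vectors.
#' @name quaternion
NULL

#' Multiply two quaternions (Hamilton product)
#'
#' @rdname quaternion
#' @return `quat_multiply()`: the product `p * q`, a length-4 numeric vector.
#' @export
#' @examples
#' quat_multiply(c(1, 0, 0, 0), c(0, 1, 0, 0))
quat_multiply <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

#' @rdname quaternion
#' @return `quat_conjugate()`: the conjugate (inverse for unit quaternions).
#' @export
quat_conjugate <- function(q) { q <- as.numeric(q); c(q[1], -q[2], -q[3], -q[4]) }

#' @rdname quaternion
#' @return `quat_normalize()`: `q` scaled to unit norm.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotation matrix of a unit quaternion (sensor-to-world)
#'
#' @rdname quaternion
#' @return `quat_to_matrix()`: the 3x3 rotation matrix `R` with
#'   `v_world = R %*% v_sensor`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a 3-vector from the sensor frame into the world frame
#'
#' @rdname quaternion
#' @param v Numeric length-3 vector in the sensor frame.
#' @return `quat_rotate()`: `v` expressed in the world frame.
#' @export
quat_rotate <- function(q, v) {
  drop(quat_to_matrix(q) %*% v)
}

#' Build a quaternion from z-y-x Euler angles
#'
#' @rdname quaternion
#' @param yaw,pitch,roll Angles in degrees (intrinsic z-y-x order).
#' @return `quat_from_euler()`: the sensor-to-world unit quaternion.
#' @export
quat_from_euler <- function(yaw, pitch, roll) {
  yaw <- as.numeric(yaw); pitch <- as.numeric(pitch); roll <- as.numeric(roll)
  hy <- yaw * pi / 360; hp <- pitch * pi / 360; hr <- roll * pi / 360
  cy <- cos(hy); sy <- sin(hy)
  cp <- cos(hp); sp <- sin(hp)
  cr <- cos(hr); sr <- sin(hr)
  # qz(yaw) * qy(pitch) * qx(roll), expanded
  c(
    cy * cp * cr + sy * sp * sr,
    cy * cp * sr - sy * sp * cr,
    cy * sp * cr + sy * cp * sr,
    sy * cp * cr - cy * sp * sr
  )
}

#' Recover z-y-x Euler angles from a unit quaternion
#'
#' Pitch is folded into `[-90, 90]` degrees by the `asin`; yaw and roll are in
#' `(-180, 180]`.  Within half a degree of the gimbal-lock poles
#' (`|pitch| = 90`) yaw and roll are not separately identifiable; callers that
#' care should flag such samples (see [fuse_orientation()]).
#'
#' @rdname quaternion
#' @return `quat_to_euler()`: named numeric vector `c(yaw, pitch, roll)`
#'   in degrees.
#' @export
quat_to_euler <- function(q) {
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  sinp <- 2 * (w * y - x * z)
  sinp <- min(1, max(-1, sinp))
  c(
    yaw   = atan2(2 * (x * y + w * z), 1 - 2 * (y^2 + z^2)) * 180 / pi,
    pitch = asin(sinp) * 180 / pi,
    roll  = atan2(2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)) * 180 / pi
  )
}

#' Geodesic angle between two unit quaternions
#'
#' @rdname quaternion
#' @return `quat_angle()`: the rotation angle in degrees needed to take one
#'   orientation into the other, in `[0, 180]`.  Antipodal quaternions
#'   (`q` and `-q`) encode the same rotation and give angle 0.
#' @export
quat_angle <- function(p, q) {
  d <- min(1, abs(sum(p * q)))
  2 * acos(d) * 180 / pi
}

#' @rdname quaternion
#' @param axis Unit 3-vector rotation axis.
#' @param angle_deg Rotation angle, degrees.
#' @return `quat_from_axis_angle()`: the corresponding unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

# Body-frame rotation vector (deg) taking q1 into q2: log map of q1^-1 * q2.
# Internal; used to synthesise gyroscope readings and to integrate them back.
quat_log_rate <- function(q1, q2) {
  dq <- quat_multiply(quat_conjugate(q1), q2)
  if (dq[1] < 0) dq <- -dq
  v <- dq[2:4]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-15) return(c(0, 0, 0))
  ang <- 2 * atan2(nv, dq[1])
  v / nv * ang * 180 / pi
}
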