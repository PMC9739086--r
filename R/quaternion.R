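#' Quaternion algebra for orientation
#'
#' Orientation everywhere in wristkin is carried by unit quaternions
#' `c(q0, q1, q2, q3)` (Hamilton convention, scalar part first), never by
#' Euler angles, so the chain of rotations in a capture is free of gimbal
#' lock.  A rotation of angle `angle` about the unit axis `axis` maps to the
#' quaternion `(cos(angle/2), axis * sin(angle/2))`.
#'
#' Frame convention: the package works in north-east-down (NED) axes.  The
#' rotation matrix [quat_to_rotation_matrix()] built from a fusion-filter
#' quaternion is taken as the earth-to-body map, and its inverse (transpose)
#' carries body-frame sensor readings into the earth frame — see
#' [rotate_body_to_earth()].
#'
#' @param axis numeric length-3 unit vector (checked to 1e-9).
#' @param angle rotation angle in radians.
#' @return `quat_from_axis_angle()` returns a unit quaternion as a numeric
#'   vector `c(q0, q1, q2, q3)`.
#' @examples
#' quat_from_axis_angle(c(0, 0, 1), pi / 2)
#' quat_multiply(quat_from_axis_angle(c(0, 0, 1), pi / 2),
#'               quat_from_axis_angle(c(0, 0, 1), pi / 2))
#' @export
quat_from_axis_angle <- function(axis, angle) {
  stopifnot(is.numeric(axis), length(axis) == 3, is.finite(angle))
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-9) {
    stop("`axis` must be a unit vector; got norm ", format(nrm, digits = 12))
  }
  quat_normalize(c(cos(angle / 2), axis * sin(angle / 2)))
}

#' Normalize a quaternion to unit norm
#'
#' @param q numeric length-4 quaternion, or an n x 4 matrix of quaternions
#'   (one per row).
#' @return The input scaled to unit norm (row-wise for matrices).
#' @export
quat_normalize <- function(q) {
  if (is.matrix(q)) {
    nrm <- sqrt(rowSums(q^2))
    if (any(nrm == 0)) stop("cannot normalize a zero quaternion")
    return(q / nrm)
  }
  nrm <- sqrt(sum(q^2))
  if (nrm == 0) stop("cannot normalize a zero quaternion")
  q / nrm
}

.check_unit_quat <- function(q, tol = 1e-6) {
  stopifnot(is.numeric(q), length(q) == 4)
  nrm <- sqrt(sum(q^2))
  if (abs(nrm - 1) > tol) {
    stop("quaternion must be unit-norm; got norm ", format(nrm, digits = 12))
  }
  invisible(q)
}

#' Hamilton product of two quaternions
#'
#' Composes rotations: `quat_multiply(q_second, q_first)` is the rotation
#' obtained by applying `q_first` and then `q_second` (the product is not
#' commutative).  The result is re-normalized to guard against drift in long
#' chains — the fusion filter composes thousands of updates per capture.
#'
#' @param q_second,q_first unit quaternions `c(q0, q1, q2, q3)`.
#' @return A unit quaternion.
#' @export
quat_multiply <- function(q_second, q_first) {
  .check_unit_quat(q_second)
  .check_unit_quat(q_first)
  quat_normalize(.quat_mul_raw(q_second, q_first))
}

# Hamilton product without pre/post checks, for hot loops.
.quat_mul_raw <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Quaternion conjugate
#'
#' For unit quaternions the conjugate is the inverse rotation, needed to
#' invert the earth-to-body map when expressing body accelerations in the
#' earth frame.
#'
#' @param q unit quaternion `c(q0, q1, q2, q3)`, or an n x 4 matrix.
#' @return The conjugate `(q0, -q1, -q2, -q3)` (row-wise for matrices).
#' @export
quat_conjugate <- function(q) {
  if (is.matrix(q)) {
    stopifnot(ncol(q) == 4)
    return(q %*% diag(c(1, -1, -1, -1)))
  }
  stopifnot(is.numeric(q), length(q) == 4)
  q * c(1, -1, -1, -1)
}

#' Rotation matrix of a quaternion
#'
#' Expands a unit quaternion into the 3 x 3 orthonormal rotation matrix
#' \deqn{R(q) = \begin{pmatrix}
#'  q_0^2+q_1^2-q_2^2-q_3^2 & 2q_1q_2-2q_0q_3 & 2q_1q_3+2q_0q_2 \\
#'  2q_1q_2+2q_0q_3 & q_0^2-q_1^2+q_2^2-q_3^2 & 2q_2q_3-2q_0q_1 \\
#'  2q_1q_3-2q_0q_2 & 2q_2q_3+2q_0q_1 & q_0^2-q_1^2-q_2^2+q_3^2
#' \end{pmatrix}}
#' Under the package's frame convention this matrix, evaluated at a fusion
#' quaternion, maps earth-frame vectors into the device (body) frame; its
#' inverse maps the other way.
#'
#' @param q unit quaternion (checked to 1e-6).
#' @return A 3 x 3 orthonormal matrix with determinant +1.
#' @export
quat_to_rotation_matrix <- function(q) {
  .check_unit_quat(q)
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * q1 * q2 - 2 * q0 * q3, 2 * q1 * q3 + 2 * q0 * q2,
    2 * q1 * q2 + 2 * q0 * q3, q0^2 - q1^2 + q2^2 - q3^2, 2 * q2 * q3 - 2 * q0 * q1,
    2 * q1 * q3 - 2 * q0 * q2, 2 * q2 * q3 + 2 * q0 * q1, q0^2 - q1^2 - q2^2 + q3^2
  ), nrow = 3, byrow = TRUE)
}

# Apply R(q) (see quat_to_rotation_matrix) to rows of an n x 3 matrix, with
# one quaternion per row of `qm` (n x 4).  Vectorized; no normalization.
.rotate_rows <- function(qm, vm) {
  q0 <- qm[, 1]; q1 <- qm[, 2]; q2 <- qm[, 3]; q3 <- qm[, 4]
  x <- vm[, 1]; y <- vm[, 2]; z <- vm[, 3]
  cbind(
    (q0^2 + q1^2 - q2^2 - q3^2) * x + 2 * (q1 * q2 - q0 * q3) * y + 2 * (q1 * q3 + q0 * q2) * z,
    2 * (q1 * q2 + q0 * q3) * x + (q0^2 - q1^2 + q2^2 - q3^2) * y + 2 * (q2 * q3 - q0 * q1) * z,
    2 * (q1 * q3 - q0 * q2) * x + 2 * (q2 * q3 + q0 * q1) * y + (q0^2 - q1^2 - q2^2 + q3^2) * z
  )
}

#' Rotate a body-frame vector into the earth frame
#'
#' Applies the inverse (transpose) of the quaternion rotation matrix to a
#' body-frame vector, expressing device accelerations in earth (NED) axes.
#' Rotations are isometries, so the norm of the input is preserved.
#'
#' @param q unit quaternion, or an n x 4 matrix of per-sample quaternions.
#' @param v_body numeric length-3 body-frame vector, or an n x 3 matrix
#'   matched row-wise with `q`.
#' @return Earth-frame vector(s), same shape as `v_body`.
#' @export
rotate_body_to_earth <- function(q, v_body) {
  if (is.matrix(q) || is.matrix(v_body)) {
    q <- if (is.matrix(q)) q else matrix(q, nrow(v_body), 4, byrow = TRUE)
    v_body <- if (is.matrix(v_body)) v_body else matrix(v_body, nrow(q), 3, byrow = TRUE)
    stopifnot(nrow(q) == nrow(v_body), ncol(q) == 4, ncol(v_body) == 3)
    return(.rotate_rows(quat_conjugate(q), v_body))
  }
  .check_unit_quat(q)
  stopifnot(is.numeric(v_body), length(v_body) == 3)
  drop(.rotate_rows(rbind(quat_conjugate(q)), rbind(v_body)))
}

#' Euler angles (yaw, pitch, roll) of a quaternion
#'
#' Aerospace ZYX decomposition in degrees, NED-consistent; used for the
#' stabilization plot of the fusion warm-up only, never in the kinematics
#' computation.  When the pitch is within 1e-9 deg of +/-90 deg the yaw and
#' roll axes align (gimbal lock) and the two angles are no longer unique;
#' such samples are flagged.
#'
#' @param q unit quaternion, or an n x 4 matrix of quaternions.
#' @return A tibble with columns `yaw`, `pitch`, `roll` (degrees) and
#'   `gimbal_degenerate` (logical), one row per quaternion.
#' @export
quat_to_euler <- function(q) {
  qm <- if (is.matrix(q)) q else rbind(q, deparse.level = 0)
  stopifnot(ncol(qm) == 4)
  dimnames(qm) <- NULL
  q0 <- qm[, 1]; q1 <- qm[, 2]; q2 <- qm[, 3]; q3 <- qm[, 4]
  sinp <- pmin(1, pmax(-1, 2 * (q0 * q2 - q3 * q1)))
  pitch <- asin(sinp) * 180 / pi
  degenerate <- abs(abs(pitch) - 90) < 1e-9
  tibble::tibble(
    yaw   = atan2(2 * (q0 * q3 + q1 * q2), 1 - 2 * (q2^2 + q3^2)) * 180 / pi,
    pitch = pitch,
    roll  = atan2(2 * (q0 * q1 + q2 * q3), 1 - 2 * (q1^2 + q2^2)) * 180 / pi,
    gimbal_degenerate = degenerate
  )
}

#' Quaternion from yaw/pitch/roll angles
#'
#' Inverse of [quat_to_euler()] away from gimbal lock: composes the ZYX
#' rotations `yaw` about down, `pitch` about east, `roll` about north.
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return A unit quaternion `c(q0, q1, q2, q3)`.
#' @export
quat_from_euler <- function(yaw, pitch, roll) {
  d <- pi / 180
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw * d)
  qy <- quat_from_axis_angle(c(0, 1, 0), pitch * d)
  qx <- quat_from_axis_angle(c(1, 0, 0), roll * d)
  quat_multiply(quat_multiply(qz, qy), qx)
}

# Rotation angle (radians) between two unit quaternions; used as the scalar
# orientation-error metric in fusion tests.
quat_angle_between <- function(qa, qb) {
  d <- abs(sum(qa * qb))
  2 * acos(pmin(1, d))
}
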