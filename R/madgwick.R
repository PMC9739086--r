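#' Fusion filter configuration
#'
#' Settings for the gradient-descent (Madgwick-type) orientation filter that
#' fuses gyroscope, accelerometer, and magnetometer readings into a unit
#' quaternion per sample.
#'
#' @param beta filter gain (dimensionless, > 0): the step size, in rad/s, at
#'   which the orientation estimate is pulled along the negative gradient of
#'   the accelerometer + magnetometer objective.  Default 0.1, the order of
#'   magnitude recommended for this filter class; lower values trust the
#'   gyroscope more during high-dynamics motion.
#' @param sample_period seconds between samples (default 0.002 s, the
#'   capture clock).
#' @param magnetic_reference earth-frame direction of the local magnetic
#'   field in NED axes (north, east, down).  Defaults to a mid-latitude
#'   northern-hemisphere field with a 60 degree dip.  Only the direction
#'   matters; it is normalized on construction.
#' @param initial_orientation unit quaternion used to seed the filter
#'   (default identity); the stabilization warm-up absorbs any
#'   initialization error.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(beta = 0.1,
                          sample_period = 0.002,
                          magnetic_reference = c(cos(60 * pi / 180), 0, sin(60 * pi / 180)),
                          initial_orientation = c(1, 0, 0, 0)) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0,
            is.numeric(sample_period), length(sample_period) == 1, sample_period > 0,
            is.numeric(magnetic_reference), length(magnetic_reference) == 3)
  .check_unit_quat(initial_orientation)
  structure(
    list(beta = beta,
         sample_period = sample_period,
         magnetic_reference = magnetic_reference / sqrt(sum(magnetic_reference^2)),
         initial_orientation = initial_orientation),
    class = "fusion_config")
}

# One filter step.  q: current unit quaternion; w: gyro rad/s; a: accel
# m/s^2; m: magnetometer (any consistent unit); beta, dt scalars.
# Measurement model: a stationary accelerometer reads the gravity reaction
# R(q) %*% c(0, 0, -1) (normalized) and the magnetometer reads R(q) %*% b,
# where R(q) is the earth-to-body matrix of quat_to_rotation_matrix() and
# b = (bx, 0, bz) is the measured field rotated to earth axes with its east
# component folded into north (standard magnetic-distortion compensation).
# The corrective step descends the gradient of the stacked residual.
.madgwick_step <- function(q, w, a, m, beta, dt) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]

  # gyro quaternion rate: qdot = 0.5 * q (x) (0, w)
  qdot <- 0.5 * c(-q1 * w[1] - q2 * w[2] - q3 * w[3],
                  q0 * w[1] + q2 * w[3] - q3 * w[2],
                  q0 * w[2] - q1 * w[3] + q3 * w[1],
                  q0 * w[3] + q1 * w[2] - q2 * w[1])

  an <- sqrt(sum(a^2))
  if (beta > 0 && an > 0) {
    a <- a / an
    mn <- sqrt(sum(m^2))
    use_mag <- mn > 0
    # gravity residual: R(q) c(0,0,-1) - a
    f1 <- -2 * (q1 * q3 + q0 * q2) - a[1]
    f2 <- -2 * (q2 * q3 - q0 * q1) - a[2]
    f3 <- -(q0^2 - q1^2 - q2^2 + q3^2) - a[3]
    # gradient = t(J) %*% f, J the analytic Jacobian of the residual in q
    g0 <- -2 * q2 * f1 + 2 * q1 * f2 - 2 * q0 * f3
    g1 <- -2 * q3 * f1 + 2 * q0 * f2 + 2 * q1 * f3
    g2 <- -2 * q0 * f1 - 2 * q3 * f2 + 2 * q2 * f3
    g3 <- -2 * q1 * f1 - 2 * q2 * f2 - 2 * q3 * f3
    if (use_mag) {
      m <- m / mn
      # earth-frame field h = t(R) m; fold east into north: b = (bx, 0, bz)
      h1 <- (q0^2 + q1^2 - q2^2 - q3^2) * m[1] + 2 * (q1 * q2 + q0 * q3) * m[2] + 2 * (q1 * q3 - q0 * q2) * m[3]
      h2 <- 2 * (q1 * q2 - q0 * q3) * m[1] + (q0^2 - q1^2 + q2^2 - q3^2) * m[2] + 2 * (q2 * q3 + q0 * q1) * m[3]
      h3 <- 2 * (q1 * q3 + q0 * q2) * m[1] + 2 * (q2 * q3 - q0 * q1) * m[2] + (q0^2 - q1^2 - q2^2 + q3^2) * m[3]
      bx <- sqrt(h1^2 + h2^2)
      bz <- h3
      # magnetic residual: R(q) c(bx, 0, bz) - m
      f4 <- bx * (q0^2 + q1^2 - q2^2 - q3^2) + 2 * bz * (q1 * q3 + q0 * q2) - m[1]
      f5 <- 2 * bx * (q1 * q2 + q0 * q3) + 2 * bz * (q2 * q3 - q0 * q1) - m[2]
      f6 <- 2 * bx * (q1 * q3 - q0 * q2) + bz * (q0^2 - q1^2 - q2^2 + q3^2) - m[3]
      g0 <- g0 + (2 * bx * q0 + 2 * bz * q2) * f4 + (2 * bx * q3 - 2 * bz * q1) * f5 + (-2 * bx * q2 + 2 * bz * q0) * f6
      g1 <- g1 + (2 * bx * q1 + 2 * bz * q3) * f4 + (2 * bx * q2 - 2 * bz * q0) * f5 + (2 * bx * q3 - 2 * bz * q1) * f6
      g2 <- g2 + (-2 * bx * q2 + 2 * bz * q0) * f4 + (2 * bx * q1 + 2 * bz * q3) * f5 + (-2 * bx * q0 - 2 * bz * q2) * f6
      g3 <- g3 + (-2 * bx * q3 + 2 * bz * q1) * f4 + (2 * bx * q0 + 2 * bz * q2) * f5 + (2 * bx * q1 + 2 * bz * q3) * f6
    }
    gn <- sqrt(g0^2 + g1^2 + g2^2 + g3^2)
    if (gn > 0) {
      qdot <- qdot - beta * c(g0, g1, g2, g3) / gn
    }
  }
  q <- q + qdot * dt
  q / sqrt(sum(q^2))
}

#' One gradient-descent fusion update
#'
#' Advances the orientation estimate by one sample: the gyroscope rate is
#' integrated through the quaternion kinematics and corrected along the
#' negative gradient of the accelerometer + magnetometer objective, scaled
#' by the gain `beta`, then normalized.  With `beta = 0` the filter reduces
#' to pure gyroscope integration.
#'
#' If the accelerometer reading is the zero vector its direction is
#' undefined; the step falls back to gyro-only propagation and warns.
#'
#' @param q_prev unit quaternion from the previous step.
#' @param gyro angular rate, rad/s, body axes (NED convention).
#' @param accel specific force, m/s^2, body axes.
#' @param mag magnetic field, gauss, body axes.
#' @param cfg a [fusion_config()].
#' @return The updated unit quaternion.
#' @export
madgwick_update <- function(q_prev, gyro, accel, mag, cfg = fusion_config()) {
  .check_unit_quat(q_prev)
  stopifnot(length(gyro) == 3, length(accel) == 3, length(mag) == 3)
  if (sum(accel^2) == 0 && cfg$beta > 0) {
    warning("zero accelerometer vector: falling back to gyro-only propagation")
  }
  .madgwick_step(q_prev, gyro, accel, mag, cfg$beta, cfg$sample_period)
}

.capture_matrices <- function(capture) {
  need <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  missing <- setdiff(need, names(capture))
  if (length(missing) > 0) {
    stop("capture is missing columns: ", paste(missing, collapse = ", "))
  }
  list(a = as.matrix(capture[c("ax", "ay", "az")]),
       g = as.matrix(capture[c("gx", "gy", "gz")]),
       m = as.matrix(capture[c("mx", "my", "mz")]))
}

#' Fuse a whole capture into an orientation track
#'
#' Runs [madgwick_update()] over every sample of a capture, starting from
#' `cfg$initial_orientation`.
#'
#' @param capture an IMU capture tibble with columns `t`, `ax`, `ay`, `az`
#'   (m/s^2), `gx`, `gy`, `gz` (rad/s), `mx`, `my`, `mz` (gauss), e.g. from
#'   [simulate_capture()] or [read_capture()].
#' @param cfg a [fusion_config()].
#' @return A tibble with columns `t`, `q0`, `q1`, `q2`, `q3`, one unit
#'   quaternion per input sample.
#' @export
fuse_capture <- function(capture, cfg = fusion_config()) {
  mats <- .capture_matrices(capture)
  n <- nrow(capture)
  stopifnot(n >= 1)
  beta <- cfg$beta
  dt <- cfg$sample_period
  qm <- matrix(NA_real_, n, 4)
  q <- cfg$initial_orientation
  n_zero_accel <- 0L
  for (i in seq_len(n)) {
    a <- mats$a[i, ]
    if (beta > 0 && a[1] == 0 && a[2] == 0 && a[3] == 0) n_zero_accel <- n_zero_accel + 1L
    q <- .madgwick_step(q, mats$g[i, ], a, mats$m[i, ], beta, dt)
    qm[i, ] <- q
  }
  if (n_zero_accel > 0) {
    warning(n_zero_accel, " sample(s) had a zero accelerometer vector; ",
            "gyro-only propagation was used there")
  }
  tibble::tibble(t = capture$t, q0 = qm[, 1], q1 = qm[, 2],
                 q2 = qm[, 3], q3 = qm[, 4])
}

#' Stabilization warm-up
#'
#' The first orientation estimates of the fusion filter are inaccurate until
#' the gradient correction has worked off the initialization error, so the
#' device waits through a warm-up phase before capturing motion.  This
#' function runs the filter over the head of a (nominally stationary)
#' capture and reports the converged orientation together with the
#' per-sample Euler history for a stabilization plot.
#'
#' Convergence is declared when, over the last second of warm-up, yaw,
#' pitch, and roll each vary by less than 0.5 degrees.
#'
#' @param capture_head capture tibble covering at least `warmup` seconds.
#' @param cfg a [fusion_config()].
#' @param warmup warm-up duration in seconds (default 20 s).
#' @return A list of class `stabilization` with elements `orientation`
#'   (unit quaternion), `euler_history` (tibble `t`, `yaw`, `pitch`, `roll`
#'   in degrees), and `converged` (logical).
#' @export
stabilize <- function(capture_head, cfg = fusion_config(), warmup = 20) {
  stopifnot(warmup > 0)
  n_needed <- ceiling(warmup / cfg$sample_period)
  if (nrow(capture_head) < n_needed) {
    stop("warm-up needs at least ", n_needed, " samples (",
         warmup, " s at ", 1 / cfg$sample_period, " Hz); capture has ",
         nrow(capture_head))
  }
  head_cap <- capture_head[seq_len(n_needed), , drop = FALSE]
  track <- fuse_capture(head_cap, cfg)
  euler <- quat_to_euler(as.matrix(track[c("q0", "q1", "q2", "q3")]))
  history <- tibble::tibble(t = track$t, yaw = euler$yaw,
                            pitch = euler$pitch, roll = euler$roll)
  last_s <- history[history$t > max(history$t) - 1, ]
  spans <- vapply(last_s[c("yaw", "pitch", "roll")], function(x) {
    # yaw wraps at +/-180; measure spread on the circle
    a <- x * pi / 180
    180 / pi * (max(atan2(sin(a - mean(a)), cos(a - mean(a)))) -
                  min(atan2(sin(a - mean(a)), cos(a - mean(a)))))
  }, numeric(1))
  structure(
    list(orientation = as.numeric(track[nrow(track), c("q0", "q1", "q2", "q3")]),
         euler_history = history,
         converged = all(spans < 0.5)),
    class = "stabilization")
}
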