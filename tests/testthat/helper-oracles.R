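# Independent oracles and small fixture builders used across the suite.

# Rodrigues rotation formula: rotate v by angle theta about unit axis k.
rodrigues_rotate <- function(v, k, theta) {
  v * cos(theta) +
    c(k[2] * v[3] - k[3] * v[2],
      k[3] * v[1] - k[1] * v[3],
      k[1] * v[2] - k[2] * v[1]) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

# axis-angle extraction from a unit quaternion
quat_axis_angle <- function(q) {
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-15) return(list(axis = c(0, 0, 1), angle = 0))
  list(axis = q[2:4] / vn, angle = 2 * atan2(vn, q[1]))
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# Naive O(n * count) zero-velocity scan: walk runs of all-axis quiet
# samples and zero velocity over every run at least `count` long.
zupt_oracle <- function(dyn_accel, velocity, limit, count) {
  quiet <- abs(dyn_accel[, 1]) < limit & abs(dyn_accel[, 2]) < limit &
    abs(dyn_accel[, 3]) < limit
  out <- velocity
  n <- length(quiet)
  s <- 1
  while (s <= n) {
    if (quiet[s]) {
      e <- s
      while (e < n && quiet[e + 1]) e <- e + 1
      if (e - s + 1 >= count) out[s:e, ] <- 0
      s <- e + 1
    } else {
      s <- s + 1
    }
  }
  out
}

# Independent implementation of the gradient-descent fusion step: same
# measurement model as the package filter, but the corrective direction is
# the numerically differentiated gradient of 0.5 * ||F(q)||^2 (central
# differences) instead of the analytic Jacobian product.
madgwick_step_fd <- function(q, w, a, m, beta, dt) {
  qdot <- 0.5 * c(-q[2] * w[1] - q[3] * w[2] - q[4] * w[3],
                  q[1] * w[1] + q[3] * w[3] - q[4] * w[2],
                  q[1] * w[2] - q[2] * w[3] + q[4] * w[1],
                  q[1] * w[3] + q[2] * w[2] - q[3] * w[1])
  an <- sqrt(sum(a^2))
  if (beta > 0 && an > 0) {
    ah <- a / an
    mh <- m / sqrt(sum(m^2))
    R <- function(qq) wristkin::quat_to_rotation_matrix(qq / sqrt(sum(qq^2)))
    h <- t(R(q)) %*% mh
    b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3])
    objective <- function(qq) {
      Rm <- matrix(c(
        qq[1]^2 + qq[2]^2 - qq[3]^2 - qq[4]^2, 2 * (qq[2] * qq[3] - qq[1] * qq[4]), 2 * (qq[2] * qq[4] + qq[1] * qq[3]),
        2 * (qq[2] * qq[3] + qq[1] * qq[4]), qq[1]^2 - qq[2]^2 + qq[3]^2 - qq[4]^2, 2 * (qq[3] * qq[4] - qq[1] * qq[2]),
        2 * (qq[2] * qq[4] - qq[1] * qq[3]), 2 * (qq[3] * qq[4] + qq[1] * qq[2]), qq[1]^2 - qq[2]^2 - qq[3]^2 + qq[4]^2
      ), 3, 3, byrow = TRUE)
      f <- c(Rm %*% c(0, 0, -1) - ah, Rm %*% b - mh)
      0.5 * sum(f^2)
    }
    eps <- 1e-6
    g <- vapply(1:4, function(k) {
      qp <- q; qm_ <- q
      qp[k] <- qp[k] + eps
      qm_[k] <- qm_[k] - eps
      (objective(qp) - objective(qm_)) / (2 * eps)
    }, numeric(1))
    gn <- sqrt(sum(g^2))
    if (gn > 0) qdot <- qdot - beta * g / gn
  }
  q <- q + qdot * dt
  q / sqrt(sum(q^2))
}

run_fd_filter <- function(capture, cfg) {
  q <- cfg$initial_orientation
  a <- as.matrix(capture[c("ax", "ay", "az")])
  g <- as.matrix(capture[c("gx", "gy", "gz")])
  m <- as.matrix(capture[c("mx", "my", "mz")])
  for (i in seq_len(nrow(capture))) {
    q <- madgwick_step_fd(q, g[i, ], a[i, ], m[i, ], cfg$beta,
                          cfg$sample_period)
  }
  q
}

# angle (deg) between two unit quaternions, double-cover aware
quat_err_deg <- function(qa, qb) {
  2 * acos(pmin(1, abs(sum(qa * qb)))) * 180 / pi
}

# Kasa algebraic circle fit; returns the fitted radius of 2D points
circle_fit_radius <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  s <- qr.solve(A, b)
  sqrt(s[3] + s[1]^2 + s[2]^2)
}

# Capture of a pure z-rotation at constant rate: accelerometer keeps
# reading straight gravity reaction (the down axis is unchanged by yaw),
# the magnetometer sweeps, the gyroscope reads the constant rate.
pure_yaw_capture <- function(rate = pi / 2, duration = 2, fs = 500,
                             g = 9.80665,
                             mag_field = 0.48 * c(cos(pi / 3), 0, sin(pi / 3))) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  th <- rate * t
  qm <- cbind(cos(th / 2), 0, 0, sin(th / 2))
  mag <- t(vapply(seq_len(n), function(i) {
    drop(wristkin::quat_to_rotation_matrix(qm[i, ]) %*% mag_field)
  }, numeric(3)))
  tibble::tibble(t = t,
                 ax = 0, ay = 0, az = -g,
                 gx = 0, gy = 0, gz = rate,
                 mx = mag[, 1], my = mag[, 2], mz = mag[, 3])
}
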