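#' Parametric ground-truth trajectory
#'
#' A trajectory spec couples a position path `p(t)` (meters, earth NED
#' frame) with an orientation path `q(t)` (unit quaternion vs. time) over a
#' fixed duration; the synthetic IMU generator samples it to manufacture the
#' 9-DoF streams a wrist-worn device would record.
#'
#' @param position_fn function of a time vector returning an n x 3 matrix
#'   of positions (m, NED).
#' @param orientation_fn function of a time vector returning an n x 4
#'   matrix of quaternions (normalized on use).
#' @param duration trajectory duration, seconds.
#' @param name preset name (informational).
#' @param velocity_fn optional analytic velocity (n x 3, m/s) for tight
#'   tests; numerical differentiation is used when absent.
#' @param segments optional tibble (`segment`, `start`, `end`) labelling
#'   phases of the motion (e.g. the release segment of a throw).
#' @return A list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(position_fn, orientation_fn, duration,
                            name = "custom", velocity_fn = NULL,
                            segments = NULL) {
  stopifnot(is.function(position_fn), is.function(orientation_fn),
            duration > 0)
  structure(
    list(position_fn = position_fn, orientation_fn = orientation_fn,
         duration = duration, name = name, velocity_fn = velocity_fn,
         segments = segments),
    class = "trajectory_spec")
}

#' Sensor noise model
#'
#' White noise, constant per-axis biases, and a slowly growing gyro bias,
#' all driven by a single seed so captures are reproducible.  Defaults are
#' plausible for a consumer MEMS 9-DoF sensor.
#'
#' @param accel_sd accelerometer white-noise standard deviation, m/s^2.
#' @param gyro_sd gyroscope white-noise standard deviation, deg/s.
#' @param mag_sd magnetometer white-noise standard deviation, gauss.
#' @param accel_bias per-axis constant accelerometer bias, m/s^2 (length 1
#'   or 3).
#' @param gyro_bias gyroscope constant bias magnitude, deg/s (spread over a
#'   random fixed direction).
#' @param gyro_drift_rate linear growth rate of the gyro bias, deg/s per s.
#' @param seed integer seed for all generated randomness.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(accel_sd = 0.05, gyro_sd = 0.2, mag_sd = 0.005,
                        accel_bias = 0, gyro_bias = 0.5,
                        gyro_drift_rate = 0.01, seed = 1L) {
  stopifnot(accel_sd >= 0, gyro_sd >= 0, mag_sd >= 0, gyro_bias >= 0,
            gyro_drift_rate >= 0)
  structure(
    list(accel_sd = accel_sd, gyro_sd = gyro_sd, mag_sd = mag_sd,
         accel_bias = rep(accel_bias, length.out = 3),
         gyro_bias = gyro_bias, gyro_drift_rate = gyro_drift_rate,
         seed = as.integer(seed)),
    class = "noise_model")
}

#' Noise-free sensor model
#'
#' Convenience wrapper: a [noise_model()] with every noise source and bias
#' set to zero.
#'
#' @param seed seed (kept for interface symmetry; no randomness is drawn).
#' @return A `noise_model`.
#' @export
noise_free <- function(seed = 1L) {
  noise_model(accel_sd = 0, gyro_sd = 0, mag_sd = 0, accel_bias = 0,
              gyro_bias = 0, gyro_drift_rate = 0, seed = seed)
}

#' Sample ground truth from a trajectory spec
#'
#' Samples position and orientation on the fixed capture clock and
#' differentiates numerically (central differences; one-sided at the ends)
#' for velocity and acceleration, so arbitrary user paths are supported.
#' Presets that carry an analytic velocity use it when
#' `derivatives = "analytic"`.
#'
#' @param spec a [trajectory_spec()].
#' @param fs sampling frequency, Hz (default 500, the 0.002 s capture
#'   clock).
#' @param derivatives `"numeric"` (default) or `"analytic"` (velocity only;
#'   falls back to numeric if the spec has none).
#' @return A tibble with columns `t`, `px`, `py`, `pz`, `vx`, `vy`, `vz`,
#'   `ax`, `ay`, `az`, `q0` .. `q3`, `speed`; `round(duration * fs)` rows.
#' @export
simulate_truth <- function(spec, fs = 500, derivatives = c("numeric", "analytic")) {
  derivatives <- match.arg(derivatives)
  stopifnot(inherits(spec, "trajectory_spec"), fs > 0)
  n <- round(spec$duration * fs)
  if (n < 2) stop("duration * fs must be at least 2 samples")
  dt <- 1 / fs
  t <- (seq_len(n) - 1) * dt
  p <- spec$position_fn(t)
  if (!all(is.finite(p))) stop("position path returned non-finite values")
  q <- quat_normalize(spec$orientation_fn(t))

  v <- .central_diff(p, dt)
  if (derivatives == "analytic" && !is.null(spec$velocity_fn)) {
    v <- spec$velocity_fn(t)
  }
  a <- .central_diff(v, dt)

  tibble::tibble(
    t = t,
    px = p[, 1], py = p[, 2], pz = p[, 3],
    vx = v[, 1], vy = v[, 2], vz = v[, 3],
    ax = a[, 1], ay = a[, 2], az = a[, 3],
    q0 = q[, 1], q1 = q[, 2], q2 = q[, 3], q3 = q[, 4],
    speed = sqrt(v[, 1]^2 + v[, 2]^2 + v[, 3]^2))
}

.central_diff <- function(m, dt) {
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (m[2, ] - m[1, ]) / dt
  d[n, ] <- (m[n, ] - m[n - 1, ]) / dt
  d
}

#' Synthesize IMU readings from ground truth
#'
#' Inverts the processing chain: body-frame accelerometer readings are the
#' specific force `R(q) (a_earth - g_vec)` (NED, gravity `(0, 0, +g)`
#' pointing down), the gyroscope reads the body angular rate implied by the
#' orientation path, and the magnetometer reads the earth field rotated
#' into the body frame, sampled-and-held at its own 40 Hz output data rate
#' (the capture clock polls faster than the magnetometer refreshes).
#' Noise and biases are then added per the [noise_model()].
#'
#' @param truth ground-truth tibble from [simulate_truth()].
#' @param noise a [noise_model()].
#' @param g gravity magnitude, m/s^2.
#' @param mag_field earth magnetic field in gauss, NED components (default:
#'   0.48 gauss with a 60 degree dip, matching [fusion_config()]'s
#'   reference direction).
#' @param mag_odr magnetometer output data rate, Hz (default 40).
#' @return An IMU capture tibble (`t`, `ax` .. `mz`) of class
#'   `imu_capture`, with attribute `sample_period`.
#' @export
truth_to_imu <- function(truth, noise = noise_model(), g = 9.80665,
                         mag_field = 0.48 * c(cos(60 * pi / 180), 0, sin(60 * pi / 180)),
                         mag_odr = 40) {
  n <- nrow(truth)
  stopifnot(n >= 2)
  dt <- truth$t[2] - truth$t[1]
  qm <- as.matrix(truth[c("q0", "q1", "q2", "q3")])
  a_e <- as.matrix(truth[c("ax", "ay", "az")])

  # specific force in body axes
  g_vec <- c(0, 0, g)
  sf_e <- sweep(a_e, 2, g_vec)
  accel <- .rotate_rows(qm, sf_e)

  # body angular rate from the quaternion path: w = 2 * Im(q* (x) qdot)
  qdot <- .central_diff(qm, dt)
  q0 <- qm[, 1]; q1 <- qm[, 2]; q2 <- qm[, 3]; q3 <- qm[, 4]
  gyro <- 2 * cbind(
    q0 * qdot[, 2] - q1 * qdot[, 1] - q2 * qdot[, 4] + q3 * qdot[, 3],
    q0 * qdot[, 3] + q1 * qdot[, 4] - q2 * qdot[, 1] - q3 * qdot[, 2],
    q0 * qdot[, 4] - q1 * qdot[, 3] + q2 * qdot[, 2] - q3 * qdot[, 1])

  # magnetometer: body-frame field, sample-and-hold at its own ODR
  mag_full <- .rotate_rows(qm, matrix(mag_field, n, 3, byrow = TRUE))
  hold_period <- floor(truth$t * mag_odr + 1e-9)
  hold_idx <- match(hold_period, hold_period) # first sample of each refresh period
  mag <- mag_full[hold_idx, , drop = FALSE]

  deg <- pi / 180
  cap <- withr::with_seed(noise$seed, {
    bias_dir <- if (noise$gyro_bias > 0 || noise$gyro_drift_rate > 0) {
      u <- stats::rnorm(3)
      u / sqrt(sum(u^2))
    } else c(0, 0, 0)
    gyro_bias <- outer(rep(1, n), bias_dir * noise$gyro_bias * deg) +
      outer(truth$t, bias_dir * noise$gyro_drift_rate * deg)
    accel_n <- accel + matrix(stats::rnorm(3 * n, sd = noise$accel_sd), n, 3) +
      outer(rep(1, n), noise$accel_bias)
    gyro_n <- gyro + matrix(stats::rnorm(3 * n, sd = noise$gyro_sd * deg), n, 3) +
      gyro_bias
    mag_n <- mag + matrix(stats::rnorm(3 * n, sd = noise$mag_sd), n, 3)
    list(a = accel_n, g = gyro_n, m = mag_n)
  })

  out <- tibble::tibble(
    t = truth$t,
    ax = cap$a[, 1], ay = cap$a[, 2], az = cap$a[, 3],
    gx = cap$g[, 1], gy = cap$g[, 2], gz = cap$g[, 3],
    mx = cap$m[, 1], my = cap$m[, 2], mz = cap$m[, 3])
  attr(out, "sample_period") <- dt
  class(out) <- c("imu_capture", class(out))
  out
}

#' Simulate a capture in one call
#'
#' [simulate_truth()] followed by [truth_to_imu()]; the ground truth is
#' attached as attribute `truth` for end-to-end comparisons.
#'
#' @inheritParams simulate_truth
#' @inheritParams truth_to_imu
#' @return An `imu_capture` tibble with attribute `truth`.
#' @export
simulate_capture <- function(spec, noise = noise_model(), fs = 500,
                             g = 9.80665, ...) {
  truth <- simulate_truth(spec, fs = fs)
  cap <- truth_to_imu(truth, noise = noise, g = g, ...)
  attr(cap, "truth") <- truth
  attr(cap, "spec_name") <- spec$name
  cap
}

# --- presets ---------------------------------------------------------------

#' Stationary trajectory preset
#'
#' Device at rest at the origin in a fixed orientation; the null case of the
#' pipeline and the input for stabilization warm-ups.
#'
#' @param duration seconds (default 6).
#' @param orientation fixed unit quaternion (default identity).
#' @return A [trajectory_spec()].
#' @export
stationary_spec <- function(duration = 6, orientation = c(1, 0, 0, 0)) {
  .check_unit_quat(orientation)
  trajectory_spec(
    position_fn = function(t) matrix(0, length(t), 3),
    orientation_fn = function(t) matrix(orientation, length(t), 4, byrow = TRUE),
    velocity_fn = function(t) matrix(0, length(t), 3),
    duration = duration, name = "stationary")
}

# smooth sin^2 bump on [t0, t1]: 0 outside, integral (t1 - t0) / 2 inside
.bump <- function(t, t0, t1) {
  s <- (t - t0) / (t1 - t0)
  ifelse(s > 0 & s < 1, sin(pi * s)^2, 0)
}

# integral of .bump from t0 to t
.bump_int <- function(t, t0, t1) {
  L <- t1 - t0
  s <- pmin(1, pmax(0, (t - t0) / L))
  L * (s / 2 - sin(2 * pi * s) / (4 * pi))
}

#' Straight out-and-back trajectory preset
#'
#' Rest, a smooth run of `distance` meters north, a pause, the mirror-image
#' return, and a final rest; orientation fixed at identity.  Used for
#' displacement-closure tests (the motion ends where it began).
#'
#' @param distance one-way displacement, m.
#' @param duration total duration, s (default 6).
#' @return A [trajectory_spec()].
#' @export
line_spec <- function(distance = 1, duration = 6) {
  stopifnot(distance > 0, duration > 0)
  u <- duration / 6 # phase unit
  # velocity bumps: out during [u, 2.5u], back during [3.5u, 5u]
  vmax <- distance / (0.75 * u) # bump integral = 1.5u / 2 = 0.75u
  vel <- function(t) {
    cbind(vmax * .bump(t, u, 2.5 * u) - vmax * .bump(t, 3.5 * u, 5 * u), 0, 0)
  }
  pos <- function(t) {
    cbind(vmax * .bump_int(t, u, 2.5 * u) - vmax * .bump_int(t, 3.5 * u, 5 * u), 0, 0)
  }
  trajectory_spec(
    position_fn = function(t) pos(t),
    orientation_fn = function(t) matrix(c(1, 0, 0, 0), length(t), 4, byrow = TRUE),
    velocity_fn = vel,
    duration = duration, name = "line_out_and_back")
}

#' Uniform circular trajectory preset
#'
#' Constant-rate motion on a horizontal circle of radius `radius` at
#' angular rate `omega`; orientation yaws with the path tangent.  The
#' closed-form centripetal acceleration `omega^2 * radius` makes this the
#' reference case for differentiation accuracy.
#'
#' @param radius circle radius, m.
#' @param omega angular rate, rad/s.
#' @param duration seconds.
#' @return A [trajectory_spec()].
#' @export
circle_spec <- function(radius = 1, omega = 2 * pi, duration = 6) {
  stopifnot(radius > 0, duration > 0)
  trajectory_spec(
    position_fn = function(t) {
      th <- omega * t
      cbind(radius * sin(th), radius * (1 - cos(th)), 0)
    },
    orientation_fn = function(t) {
      th <- omega * t
      cbind(cos(th / 2), 0, 0, sin(th / 2))
    },
    velocity_fn = function(t) {
      th <- omega * t
      cbind(radius * omega * cos(th), radius * omega * sin(th), 0)
    },
    duration = duration, name = "circle")
}

#' Horizontal arc trajectory preset
#'
#' Rest, one smooth traversal of `angle` radians on a circle of radius
#' `radius`, rest: the end-to-end test case for top-view curvature
#' recovery (the reconstructed XY path should have the preset's radius).
#'
#' @param radius circle radius, m.
#' @param angle arc swept, radians (default 2 * pi / 3).
#' @param duration seconds (default 6).
#' @return A [trajectory_spec()].
#' @export
arc_spec <- function(radius = 1, angle = 2 * pi / 3, duration = 6) {
  stopifnot(radius > 0, angle > 0, duration > 0)
  u <- duration / 6
  t0 <- 1.5 * u; t1 <- 4.5 * u
  wmax <- angle / ((t1 - t0) / 2)
  theta <- function(t) wmax * .bump_int(t, t0, t1)
  omega <- function(t) wmax * .bump(t, t0, t1)
  trajectory_spec(
    position_fn = function(t) {
      th <- theta(t)
      cbind(radius * sin(th), radius * (1 - cos(th)), 0)
    },
    orientation_fn = function(t) {
      th <- theta(t)
      cbind(cos(th / 2), 0, 0, sin(th / 2))
    },
    velocity_fn = function(t) {
      th <- theta(t); w <- omega(t)
      cbind(radius * w * cos(th), radius * w * sin(th), 0)
    },
    duration = duration, name = "arc")
}

#' Discus-throw trajectory preset
#'
#' Emulates the wrist path of a discus throw on a circle of radius
#' `radius`: an initial stationary hold, a reverse half-arc wind-up, a
#' pause at the direction change, a forward accelerating turn, a release
#' segment peaking at `release_speed`, and a final deceleration to rest.
#' The ground-truth speed profile has three local maxima — wind-up, turn,
#' and release — with the global maximum in the release segment; the arm
#' also lifts slightly during release (visible in the side view).
#'
#' Phase boundaries scale with `duration` (default 6 s: hold to 0.8 s,
#' wind-up 0.8-2.0 s, pause 2.0-2.3 s, turn 2.3-3.6 s, release 3.6-4.8 s,
#' rest 4.8-6 s).
#'
#' @param radius wrist rotation radius, m (default 0.9, arm plus shoulder
#'   lever of an adult thrower).
#' @param windup_fraction 0-1: fraction of a half circumference swept in
#'   reverse during the wind-up (0 suppresses the wind-up peak entirely).
#' @param release_speed peak wrist speed at release, m/s (default 12,
#'   an amateur-thrower hand speed).
#' @param duration capture duration, s (default 6: 3000 samples at the
#'   0.002 s clock).
#' @return A [trajectory_spec()] with a `segments` table labelling the
#'   phases (including `release`).
#' @export
discus_spec <- function(radius = 0.9, windup_fraction = 1,
                        release_speed = 12, duration = 6) {
  stopifnot(radius > 0, release_speed > 0,
            windup_fraction >= 0, windup_fraction <= 1)
  # peak angular rate must stay within a +/-2000 deg/s gyroscope full scale
  w_peak <- release_speed / radius
  if (w_peak > 2000 * pi / 180) {
    stop("release_speed ", release_speed, " m/s on radius ", radius,
         " m needs ", round(w_peak * 180 / pi), " deg/s angular rate, ",
         "beyond the 2000 deg/s gyroscope full scale: infeasible kinematics")
  }
  u <- duration / 6
  seg <- tibble::tibble(
    segment = c("hold", "windup", "pause", "turn", "release", "rest"),
    start = c(0, 0.8, 2.0, 2.3, 3.6, 4.8) * u,
    end   = c(0.8, 2.0, 2.3, 3.6, 4.8, 6.0) * u)

  w_windup <- windup_fraction * pi / ((1.2 * u) / 2) # reverse arc = wf * pi
  w_turn <- 0.5 * release_speed / radius
  w_rel <- release_speed / radius
  lift <- 0.25 # m of arm elevation during release

  omega <- function(t) {
    -w_windup * .bump(t, 0.8 * u, 2.0 * u) +
      w_turn * .bump(t, 2.3 * u, 3.6 * u) +
      w_rel * .bump(t, 3.6 * u, 4.8 * u)
  }
  theta <- function(t) {
    -w_windup * .bump_int(t, 0.8 * u, 2.0 * u) +
      w_turn * .bump_int(t, 2.3 * u, 3.6 * u) +
      w_rel * .bump_int(t, 3.6 * u, 4.8 * u)
  }
  zlift <- function(t) -lift * .bump(t, 3.6 * u, 4.8 * u)
  zlift_dot <- function(t) {
    s <- (t - 3.6 * u) / (1.2 * u)
    ifelse(s > 0 & s < 1,
           -lift * pi / (1.2 * u) * sin(2 * pi * s), 0)
  }

  trajectory_spec(
    position_fn = function(t) {
      th <- theta(t)
      cbind(radius * sin(th), radius * (1 - cos(th)), zlift(t))
    },
    orientation_fn = function(t) {
      th <- theta(t)
      cbind(cos(th / 2), 0, 0, sin(th / 2))
    },
    velocity_fn = function(t) {
      th <- theta(t); w <- omega(t)
      cbind(radius * w * cos(th), radius * w * sin(th), zlift_dot(t))
    },
    duration = duration, name = "discus_throw", segments = seg)
}

#' Built-in trajectory presets
#'
#' @return Named list of preset constructor functions.
#' @export
trajectory_presets <- function() {
  list(stationary = stationary_spec, line = line_spec, circle = circle_spec,
       arc = arc_spec, discus = discus_spec)
}

#' Count local maxima of a speed profile
#'
#' Brute-force scan for strict local maxima of a (lightly thresholded)
#' speed profile; used to verify the three-peak structure of a throw.
#' Plateaus are collapsed before scanning, and peaks below `min_height`
#' are ignored.
#'
#' @param speed numeric vector, m/s.
#' @param min_height ignore maxima below this value (default 2% of the
#'   profile maximum).
#' @return Integer count of local maxima.
#' @export
count_speed_peaks <- function(speed, min_height = 0.02 * max(speed)) {
  r <- rle(speed)
  v <- r$values
  if (length(v) < 3) return(sum(v > min_height & v >= max(v)))
  peaks <- 0L
  for (i in 2:(length(v) - 1)) {
    if (v[i] > v[i - 1] && v[i] > v[i + 1] && v[i] > min_height) {
      peaks <- peaks + 1L
    }
  }
  peaks
}
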