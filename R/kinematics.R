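#' Pipeline configuration
#'
#' Tunable parameters of the capture-processing chain.
#'
#' @param smoothing_window `N`, the number of trailing samples averaged by
#'   the acceleration noise filter (default 50 samples = 100 ms at 500 Hz).
#' @param smoothing_type `"boxcar"` (default): the trailing mean of the last
#'   `N` samples, recomputed at every sample; `"exponential"`: a true
#'   exponentially weighted moving average with decay `2 / (N + 1)`, for
#'   users who want exponential weighting rather than the equal-weight
#'   window.
#' @param highpass_cutoff cutoff frequency in Hz of the high-pass (DC
#'   removal) filter applied to velocity (default 50 Hz, the device's
#'   setting).  Note: for trajectory reconstruction of sub-5 Hz human motion
#'   a drift-removal cutoff well below the motion band (e.g. 0.1 Hz) is the
#'   physically sensible choice; see the methods vignette.
#' @param highpass_order filter order (default 1: a single-pole high-pass).
#' @param zupt_limit zero-velocity window half-width in m/s^2 (default 0.3).
#' @param zupt_count minimum run of consecutive in-window samples before
#'   velocity is declared zero (default 60 samples = 120 ms).
#' @param gravity gravity magnitude in m/s^2 (default standard 9.80665).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing_window = 50,
                            smoothing_type = c("boxcar", "exponential"),
                            highpass_cutoff = 50,
                            highpass_order = 1,
                            zupt_limit = 0.3,
                            zupt_count = 60,
                            gravity = 9.80665) {
  smoothing_type <- match.arg(smoothing_type)
  stopifnot(smoothing_window >= 1, highpass_cutoff > 0, highpass_order >= 1,
            zupt_limit > 0, zupt_count >= 1, gravity > 0)
  structure(
    list(smoothing_window = as.integer(smoothing_window),
         smoothing_type = smoothing_type,
         highpass_cutoff = highpass_cutoff,
         highpass_order = as.integer(highpass_order),
         zupt_limit = zupt_limit,
         zupt_count = as.integer(zupt_count),
         gravity = gravity),
    class = "pipeline_config")
}

.as_xyz_matrix <- function(x, what = "input") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) %% 3 == 0) {
    x <- matrix(x, ncol = 3, byrow = TRUE)
  }
  if (!is.matrix(x) || ncol(x) != 3) {
    stop(what, " must be an n x 3 matrix (or 3-column data frame)")
  }
  x
}

#' Remove gravity from earth-frame accelerometer readings
#'
#' An accelerometer measures specific force: in NED axes (down positive) a
#' stationary sensor reads `(0, 0, -g)` once rotated into the earth frame.
#' Subtracting that constant gravity reaction leaves the dynamic
#' acceleration actually produced by the motion.
#'
#' @param accel_earth n x 3 matrix (or data frame) of earth-frame specific
#'   force, m/s^2, columns north/east/down.
#' @param g gravity magnitude in m/s^2.
#' @return An n x 3 matrix of dynamic acceleration.
#' @export
remove_gravity <- function(accel_earth, g = 9.80665) {
  m <- .as_xyz_matrix(accel_earth, "accel_earth")
  m[, 3] <- m[, 3] + g
  m
}

#' Moving-average acceleration smoothing
#'
#' Causal noise-reduction filter: at every sample the mean of the trailing
#' `n` samples is taken (the window "moves" with each new sample).  During
#' startup, while fewer than `n` samples exist, the mean of the samples so
#' far is used.  The `"exponential"` variant replaces the equal-weight
#' window with weights decaying by `2 / (n + 1)` per sample.
#'
#' @param signal numeric vector.
#' @param n window length in samples (1 <= n <= length(signal)).
#' @param type `"boxcar"` (default) or `"exponential"`.
#' @return Numeric vector, same length as `signal`.
#' @export
smooth_acceleration <- function(signal, n = 50, type = c("boxcar", "exponential")) {
  type <- match.arg(type)
  stopifnot(is.numeric(signal), n >= 1)
  n <- as.integer(n)
  if (n > length(signal)) {
    stop("window n = ", n, " exceeds signal length ", length(signal))
  }
  if (type == "exponential") {
    lambda <- 2 / (n + 1)
    return(as.numeric(stats::filter(lambda * signal, 1 - lambda,
                                    method = "recursive", init = signal[1])))
  }
  cs <- cumsum(signal)
  idx <- seq_along(signal)
  out <- cs / idx
  if (n > 1 && length(signal) > n) {
    i <- (n + 1):length(signal)
    out[i] <- (cs[i] - cs[i - n]) / n
  }
  out
}

#' Rectangle-rule integration
#'
#' Cumulative integral by summing rectangles whose sides are the
#' instantaneous signal values and the sampling interval; used both for
#' acceleration to velocity and for velocity to position (position is
#' integrated unfiltered by design).
#'
#' @param signal numeric vector (integrand samples).
#' @param dt sampling interval, seconds (> 0).
#' @param initial value of the integral before the first sample (default 0).
#' @return Numeric vector: `initial + dt * cumsum(signal)`.
#' @export
integrate_rectangles <- function(signal, dt, initial = 0) {
  stopifnot(is.numeric(signal), dt > 0)
  initial + dt * cumsum(signal)
}

#' High-pass (DC removal) filtering of velocity
#'
#' Integration accumulates every acceleration error into a velocity offset
#' or ramp; a high-pass filter removes this DC/drift component so that a
#' stop-start-stop motion ends back at zero velocity.  Implemented as a
#' Butterworth high-pass (default first order, i.e. single-pole) designed
#' with the `signal` package.
#'
#' @param velocity numeric vector, m/s.
#' @param cutoff cutoff frequency, Hz (0 < cutoff < fs / 2).
#' @param fs sampling frequency, Hz.
#' @param order filter order (default 1).
#' @return Filtered numeric vector, same length.
#' @export
remove_dc <- function(velocity, cutoff, fs, order = 1) {
  stopifnot(is.numeric(velocity), cutoff > 0, fs > 0)
  if (cutoff >= fs / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filter(bf, velocity))
}

#' Zero-velocity update (ZUPT)
#'
#' A stationary IMU never reads exactly zero acceleration, so integrated
#' velocity keeps creeping.  Wherever every dynamic-acceleration component
#' stays strictly inside `(-limit, +limit)` for at least `count` consecutive
#' samples, the device is declared stationary and the velocity over that
#' whole run is forced to exactly 0.0; all other samples pass unchanged.
#'
#' @param dyn_accel n x 3 matrix (or data frame) of dynamic acceleration,
#'   m/s^2 (the smoothed signal available at this stage of the chain).
#' @param velocity n x 3 matrix (or data frame) of velocity, m/s.
#' @param limit window half-width, m/s^2 (default 0.3).
#' @param count minimum run length in samples (default 60).
#' @return An n x 3 velocity matrix with attribute `zupt_mask`, the logical
#'   vector marking the zeroed samples.
#' @export
zero_velocity_update <- function(dyn_accel, velocity, limit = 0.3, count = 60) {
  a <- .as_xyz_matrix(dyn_accel, "dyn_accel")
  v <- .as_xyz_matrix(velocity, "velocity")
  stopifnot(nrow(a) == nrow(v), limit > 0, count >= 1)
  quiet <- abs(a[, 1]) < limit & abs(a[, 2]) < limit & abs(a[, 3]) < limit
  mask <- logical(nrow(v))
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= count
  for (j in which(keep)) mask[starts[j]:ends[j]] <- TRUE
  v[mask, ] <- 0
  attr(v, "zupt_mask") <- mask
  v
}

#' Instantaneous speed
#'
#' Per-sample Euclidean norm of the three velocity components,
#' `sqrt(vx^2 + vy^2 + vz^2)`.
#'
#' @param vx,vy,vz numeric vectors of equal length, m/s.
#' @return Nonnegative numeric vector of speeds, m/s.
#' @export
speed_magnitude <- function(vx, vy, vz) {
  stopifnot(length(vx) == length(vy), length(vy) == length(vz))
  sqrt(vx^2 + vy^2 + vz^2)
}

#' Process a capture into a kinematic track
#'
#' The full processing chain, in order: (1) fuse the 9-DoF samples into
#' per-sample orientation quaternions; (2) rotate body accelerations into
#' the earth frame; (3) subtract gravity, leaving dynamic acceleration;
#' (4) smooth each axis with the moving-average filter; (5) integrate to
#' velocity by the rectangle rule; (6) high-pass the velocity to remove the
#' drift/DC component; (7) apply the zero-velocity update; (8) take the
#' per-sample speed magnitude; (9) integrate velocity to position, anchored
#' so the movement begins at the origin (0, 0, 0).  Position is never
#' filtered: any further filtering would erase genuine displacement.
#'
#' @param capture IMU capture tibble (see [fuse_capture()] for the column
#'   contract).
#' @param fusion_cfg a [fusion_config()].
#' @param cfg a [pipeline_config()].
#' @return A tibble of class `kinematic_track` with columns `t`, `ax_e`,
#'   `ay_e`, `az_e` (smoothed earth-frame dynamic acceleration, m/s^2),
#'   `vx`, `vy`, `vz` (m/s), `x`, `y`, `z` (m), `speed` (m/s), and
#'   attributes `zupt_mask`, `orientation` (n x 4 quaternion matrix),
#'   `sample_period`, `pipeline_config`, `fusion_config`.
#' @examples
#' cap <- simulate_capture(stationary_spec(duration = 1),
#'                         noise = noise_model(seed = 1))
#' trk <- process_capture(cap, cfg = pipeline_config(highpass_cutoff = 0.1))
#' glance(trk)
#' @export
process_capture <- function(capture, fusion_cfg = fusion_config(),
                            cfg = pipeline_config()) {
  stopifnot(nrow(capture) >= cfg$smoothing_window)
  dt <- fusion_cfg$sample_period
  fs <- 1 / dt

  stage <- "data fusion"
  track <- tryCatch({
    qtrack <- fuse_capture(capture, fusion_cfg)
    qm <- as.matrix(qtrack[c("q0", "q1", "q2", "q3")])

    stage <- "rotation to earth frame"
    accel_body <- as.matrix(capture[c("ax", "ay", "az")])
    accel_earth <- rotate_body_to_earth(qm, accel_body)

    stage <- "gravity suppression"
    dyn <- remove_gravity(accel_earth, cfg$gravity)

    stage <- "acceleration filtering"
    dyn_s <- apply(dyn, 2, smooth_acceleration,
                   n = cfg$smoothing_window, type = cfg$smoothing_type)

    stage <- "velocity integration"
    vel <- apply(dyn_s, 2, integrate_rectangles, dt = dt, initial = 0)

    stage <- "DC filtering"
    vel <- apply(vel, 2, remove_dc, cutoff = cfg$highpass_cutoff, fs = fs,
                 order = cfg$highpass_order)

    stage <- "zero-velocity update"
    vel <- zero_velocity_update(dyn_s, vel,
                                limit = cfg$zupt_limit, count = cfg$zupt_count)
    mask <- attr(vel, "zupt_mask")

    stage <- "speed calculation"
    speed <- speed_magnitude(vel[, 1], vel[, 2], vel[, 3])

    stage <- "position integration"
    pos <- apply(vel, 2, integrate_rectangles, dt = dt, initial = 0)
    pos <- sweep(pos, 2, pos[1, ]) # movement begins at (0, 0, 0)

    out <- tibble::tibble(
      t = capture$t,
      ax_e = dyn_s[, 1], ay_e = dyn_s[, 2], az_e = dyn_s[, 3],
      vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      speed = speed)
    attr(out, "zupt_mask") <- mask
    attr(out, "orientation") <- qm
    attr(out, "sample_period") <- dt
    attr(out, "pipeline_config") <- cfg
    attr(out, "fusion_config") <- fusion_cfg
    class(out) <- c("kinematic_track", class(out))
    out
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  track
}
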