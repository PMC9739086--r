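test_that("stationary truth has zero velocity and acceleration", {
  truth <- simulate_truth(stationary_spec(duration = 2))
  expect_equal(nrow(truth), 1000)
  expect_true(all(truth[c("vx", "vy", "vz", "ax", "ay", "az")] == 0))
  expect_true(all(truth$speed == 0))
})

test_that("central differences are exact on constant-velocity paths", {
  spec <- trajectory_spec(
    position_fn = function(t) cbind(0.7 * t, -0.2 * t, 0.1 * t),
    orientation_fn = function(t) matrix(c(1, 0, 0, 0), length(t), 4,
                                        byrow = TRUE),
    duration = 2)
  truth <- simulate_truth(spec)
  i <- 2:(nrow(truth) - 1)
  expect_equal(truth$vx[i], rep(0.7, length(i)), tolerance = 1e-6)
  expect_equal(truth$vy[i], rep(-0.2, length(i)), tolerance = 1e-6)
  expect_lt(max(abs(as.matrix(truth[i, c("ax", "ay", "az")]))), 1e-6)
})

test_that("uniform circular motion recovers the centripetal acceleration", {
  r <- 0.8; w <- 3
  truth <- simulate_truth(circle_spec(radius = r, omega = w, duration = 4))
  i <- 3:(nrow(truth) - 2)
  a_mag <- sqrt(truth$ax^2 + truth$ay^2 + truth$az^2)[i]
  expect_equal(mean(a_mag), w^2 * r, tolerance = 1e-3)
  expect_lt(max(abs(a_mag - w^2 * r)) / (w^2 * r), 1e-3)
})

test_that("stationary noise-free IMU reads gravity reaction, zero rate, rotated field", {
  q_tilt <- quat_from_axis_angle(c(0, 1, 0), 0.4)
  cap <- simulate_capture(stationary_spec(duration = 1, orientation = q_tilt),
                          noise = noise_free())
  g <- 9.80665
  expected_a <- drop(quat_to_rotation_matrix(q_tilt) %*% c(0, 0, -g))
  expect_equal(as.numeric(cap[500, c("ax", "ay", "az")]), expected_a,
               tolerance = 1e-9)
  expect_lt(max(abs(as.matrix(cap[c("gx", "gy", "gz")]))), 1e-9)
  mref <- 0.48 * c(cos(pi / 3), 0, sin(pi / 3))
  expected_m <- drop(quat_to_rotation_matrix(q_tilt) %*% mref)
  expect_equal(as.numeric(cap[500, c("mx", "my", "mz")]), expected_m,
               tolerance = 1e-9)
})

test_that("magnetometer output is sampled-and-held at its 40 Hz data rate", {
  cap <- simulate_capture(circle_spec(duration = 1), noise = noise_free())
  # at 500 Hz capture and 40 Hz magnetometer: at most 41 distinct readings
  expect_lte(length(unique(cap$mx)), 41)
  expect_gt(length(unique(cap$mx)), 30)
  # accelerometer has no such quantization
  expect_gt(length(unique(cap$ax)), 400)
})

test_that("equal seeds give bit-identical captures, different seeds differ", {
  spec <- discus_spec()
  c1 <- simulate_capture(spec, noise = noise_model(seed = 5))
  c2 <- simulate_capture(spec, noise = noise_model(seed = 5))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- simulate_capture(spec, noise = noise_model(seed = 6))
  expect_false(identical(c1$ax, c3$ax))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::rnorm(1)
  set.seed(123)
  invisible(simulate_capture(stationary_spec(1), noise = noise_model(seed = 99)))
  expect_identical(stats::rnorm(1), before)
})

test_that("discus preset has the three-peak speed structure of a throw", {
  spec <- discus_spec()
  truth <- simulate_truth(spec)
  expect_equal(nrow(truth), 3000)
  expect_equal(truth$t[2] - truth$t[1], 0.002)
  expect_equal(count_speed_peaks(truth$speed), 3)
  # global maximum falls inside the release segment and hits release_speed
  rel <- spec$segments[spec$segments$segment == "release", ]
  t_peak <- truth$t[which.max(truth$speed)]
  expect_gte(t_peak, rel$start)
  expect_lte(t_peak, rel$end)
  expect_equal(max(truth$speed), 12, tolerance = 0.01)
  # throw starts and ends at rest
  expect_equal(truth$speed[1], 0)
  expect_lt(truth$speed[3000], 1e-6)
})

test_that("suppressing the wind-up removes the first speed peak", {
  truth <- simulate_truth(discus_spec(windup_fraction = 0))
  expect_equal(count_speed_peaks(truth$speed), 2)
})

test_that("infeasible release kinematics are rejected", {
  # 40 m/s on a 0.9 m radius needs > 2000 deg/s of angular rate
  expect_error(discus_spec(release_speed = 40), "infeasible")
  expect_silent(discus_spec(release_speed = 12))
})

test_that("the generator and pipeline close the loop on dynamic acceleration", {
  cap <- simulate_capture(discus_spec(), noise = noise_free())
  truth <- attr(cap, "truth")
  qtrk <- fuse_capture(cap, fusion_config())
  qm <- as.matrix(qtrk[paste0("q", 0:3)])
  a_earth <- rotate_body_to_earth(qm, as.matrix(cap[c("ax", "ay", "az")]))
  dyn <- remove_gravity(a_earth, 9.80665)
  a_true <- as.matrix(truth[c("ax", "ay", "az")])
  rel_rms <- sqrt(mean((dyn - a_true)^2)) / sqrt(mean(a_true^2))
  expect_lt(rel_rms, 0.02)
})

test_that("non-finite paths are rejected", {
  spec <- trajectory_spec(
    position_fn = function(t) cbind(t, 0 * t, sqrt(t - 1)),
    orientation_fn = function(t) matrix(c(1, 0, 0, 0), length(t), 4,
                                        byrow = TRUE),
    duration = 2)
  suppressWarnings(expect_error(simulate_truth(spec), "non-finite"))
})
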