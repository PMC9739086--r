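test_that("gravity removal leaves dynamic acceleration in NED axes", {
  g <- 9.80665
  # stationary: earth-frame specific force is (0, 0, -g)
  sf <- matrix(rep(c(0, 0, -g), 10), ncol = 3, byrow = TRUE)
  expect_equal(remove_gravity(sf, g), matrix(0, 10, 3))
  # free fall: specific force 0 -> dynamic acceleration magnitude g (down)
  ff <- remove_gravity(matrix(0, 5, 3), g)
  expect_equal(sqrt(rowSums(ff^2)), rep(g, 5))
  # adding the gravity reaction back is the identity
  set.seed(7)
  dyn <- matrix(stats::rnorm(30), 10, 3)
  sf2 <- sweep(dyn, 2, c(0, 0, g)) # dynamic minus gravity vector = specific force
  expect_equal(remove_gravity(sf2, g), dyn, tolerance = 1e-12)
})

test_that("moving mean reproduces windowed brute force and reduces variance", {
  expect_equal(smooth_acceleration(rep(3.5, 100), 50), rep(3.5, 100))
  # unit impulse spreads as 1/N over the trailing window
  x <- numeric(200)
  x[100] <- 1
  y <- smooth_acceleration(x, 50)
  expect_equal(y[100:149], rep(1 / 50, 50))
  expect_equal(y[150:200], rep(0, 51))
  # brute-force trailing mean on random input
  set.seed(8)
  x <- stats::rnorm(300)
  y <- smooth_acceleration(x, 50)
  brute <- vapply(seq_along(x), function(i) mean(x[max(1, i - 49):i]),
                  numeric(1))
  expect_equal(y, brute, tolerance = 1e-12)
  # white-noise variance drops by the window length
  set.seed(9)
  x <- stats::rnorm(1e5)
  y <- smooth_acceleration(x, 50)
  expect_equal(stats::var(y[50:1e5]), 1 / 50, tolerance = 0.15)
  expect_error(smooth_acceleration(1:10, 11), "exceeds")
})

test_that("exponential smoothing variant preserves constants and is causal", {
  expect_equal(smooth_acceleration(rep(2, 50), 10, type = "exponential"),
               rep(2, 50))
  x <- c(numeric(50), rep(1, 50))
  y <- smooth_acceleration(x, 10, type = "exponential")
  expect_true(all(y[1:50] == 0))
  expect_true(all(diff(y[50:100]) >= 0))
})

test_that("rectangle integration is exact for constants and bounded on ramps", {
  v <- integrate_rectangles(rep(2, 500), dt = 0.002, initial = 0)
  expect_equal(v[500], 2.0)
  expect_equal(integrate_rectangles(numeric(100), dt = 0.01, initial = 1.5),
               rep(1.5, 100))
  # linear ramp vs closed-form quadratic: left-rule error within one
  # rectangle of area per unit time
  dt <- 0.002
  t <- seq(0, 1, by = dt)
  v <- integrate_rectangles(t, dt = dt)
  expect_lt(max(abs(v - (t^2 / 2 + t * dt))), max(t) * dt + 1e-12)
})

test_that("high-pass filtering rejects DC and passes the high band", {
  fs <- 500
  y <- remove_dc(rep(1, 2000), cutoff = 50, fs = fs)
  expect_lt(max(abs(y[500:2000])), 0.01)
  expect_equal(remove_dc(numeric(100), 50, fs), numeric(100))
  # 200 Hz sinusoid is well above a 50 Hz cutoff: amplitude within 5%
  t <- seq(0, 4, by = 1 / fs)
  y <- remove_dc(sin(2 * pi * 200 * t), cutoff = 50, fs = fs)
  expect_equal(max(abs(y[1000:2000])), 1, tolerance = 0.05)
  expect_error(remove_dc(1:10, cutoff = 250, fs = 500), "Nyquist")
})

test_that("zero-velocity update zeroes exactly the long quiet runs", {
  # a 100-sample all-quiet stretch with nonzero velocity is fully zeroed
  a <- matrix(stats::runif(300, -0.29, 0.29), 100, 3)
  v <- matrix(1.5, 100, 3)
  out <- zero_velocity_update(a, v, limit = 0.3, count = 60)
  expect_true(all(out == 0))
  expect_true(all(attr(out, "zupt_mask")))

  # 59 quiet samples bracketed by motion stay untouched
  a2 <- rbind(matrix(5, 3, 3), matrix(0, 59, 3), matrix(5, 3, 3))
  v2 <- matrix(2, 65, 3)
  out2 <- zero_velocity_update(a2, v2, limit = 0.3, count = 60)
  expect_equal(out2, v2, ignore_attr = TRUE)
  expect_false(any(attr(out2, "zupt_mask")))
})

test_that("zero-velocity update matches the naive run scanner on random input", {
  set.seed(10)
  for (case in 1:300) {
    n <- sample(30:150, 1)
    count <- sample(5:20, 1)
    # mixture heavy in near-quiet samples so runs of all lengths occur
    a <- matrix(ifelse(stats::runif(n * 3) < 0.8,
                       stats::runif(n * 3, -0.25, 0.25),
                       stats::runif(n * 3, -3, 3)), n, 3)
    v <- matrix(stats::rnorm(n * 3), n, 3)
    out <- zero_velocity_update(a, v, limit = 0.3, count = count)
    expect_equal(unclass(out), zupt_oracle(a, v, 0.3, count),
                 ignore_attr = TRUE)
  }
})

test_that("speed magnitude is the Euclidean norm with its symmetries", {
  expect_equal(speed_magnitude(3, 4, 0), 5)
  expect_equal(speed_magnitude(0, 0, 0), 0)
  set.seed(11)
  vx <- stats::rnorm(50); vy <- stats::rnorm(50); vz <- stats::rnorm(50)
  s <- speed_magnitude(vx, vy, vz)
  expect_true(all(s >= 0))
  expect_equal(s, speed_magnitude(vz, -vx, vy))
})

test_that("a stationary capture processes to the null track", {
  cap <- simulate_capture(stationary_spec(duration = 6), noise = noise_free())
  trk <- process_capture(cap, fusion_config(),
                         pipeline_config(highpass_cutoff = 0.1))
  expect_equal(nrow(trk), nrow(cap))
  expect_equal(as.numeric(trk[1, c("x", "y", "z")]), c(0, 0, 0))
  expect_lt(glance(trk)$net_displacement, 0.05)
  expect_true(all(trk$speed == 0))
  # speed is exactly zero wherever ZUPT zeroed the velocity
  mask <- attr(trk, "zupt_mask")
  expect_true(all(trk$speed[mask] == 0))
})

test_that("processing is deterministic: identical inputs give identical tracks", {
  cap <- simulate_capture(line_spec(distance = 0.5, duration = 3),
                          noise = noise_model(seed = 12))
  t1 <- process_capture(cap, fusion_config(), pipeline_config())
  t2 <- process_capture(cap, fusion_config(), pipeline_config())
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("out-and-back motion closes near the origin with zero end velocity", {
  cap <- simulate_capture(line_spec(distance = 1, duration = 6),
                          noise = noise_free())
  # with exact orientation (pure gyro on a noise-free stream) the
  # integration chain itself closes to well under the travelled distance
  trk0 <- process_capture(cap, fusion_config(beta = 0),
                          pipeline_config(highpass_cutoff = 0.02))
  expect_gt(max(abs(trk0$x)), 0.8)            # the 1 m excursion is seen
  expect_lt(glance(trk0)$net_displacement, 0.2)
  # at the default gain the accelerometer correction during dynamics adds
  # tilt error; closure degrades but stays inside half the excursion
  trk <- process_capture(cap, fusion_config(),
                         pipeline_config(highpass_cutoff = 0.1))
  expect_lt(glance(trk)$net_displacement, 0.5)
  n <- nrow(trk)
  expect_equal(as.numeric(trk[n, c("vx", "vy", "vz")]), c(0, 0, 0))
})

test_that("reconstructed top-view curvature matches the arc radius", {
  cap <- simulate_capture(arc_spec(radius = 1), noise = noise_free())
  trk <- process_capture(cap, fusion_config(),
                         pipeline_config(highpass_cutoff = 0.1))
  moving <- trk$speed > 0.3
  r_est <- circle_fit_radius(cbind(trk$x, trk$y)[moving, ])
  expect_equal(r_est, 1, tolerance = 0.2)
})

test_that("doubling accelerometer noise does not improve position accuracy", {
  # a stationary capture with the zero-velocity window effectively disabled
  # isolates the noise-driven drift: the truth contributes nothing
  final_err <- function(sd, seed) {
    cap <- simulate_capture(stationary_spec(duration = 3),
                            noise = noise_model(accel_sd = sd, seed = seed))
    trk <- process_capture(cap, fusion_config(),
                           pipeline_config(highpass_cutoff = 0.1,
                                           zupt_limit = 0.001))
    glance(trk)$net_displacement
  }
  errs <- vapply(1:20, function(s) {
    c(final_err(0.05, s), final_err(0.10, s))
  }, numeric(2))
  expect_lte(stats::median(errs[1, ]), stats::median(errs[2, ]) + 1e-12)
})

test_that("pipeline errors name the failing stage", {
  cap <- simulate_capture(stationary_spec(duration = 1), noise = noise_free())
  bad <- pipeline_config()
  bad$highpass_cutoff <- 400 # beyond Nyquist at 500 Hz
  expect_error(process_capture(cap, fusion_config(), bad), "DC filtering")
})
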