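test_that("axis-angle construction matches the half-angle formula", {
  expect_equal(quat_from_axis_angle(c(0, 0, 1), 0), c(1, 0, 0, 0))
  expect_equal(quat_from_axis_angle(c(0, 0, 1), pi), c(0, 0, 0, 1),
               tolerance = 1e-12)
  expect_equal(quat_from_axis_angle(c(1, 0, 0), pi / 2),
               c(sqrt(2) / 2, sqrt(2) / 2, 0, 0), tolerance = 1e-12)
  expect_error(quat_from_axis_angle(c(1, 1, 0), 1), "unit vector")
})

test_that("Hamilton product composes rotations and respects the identity", {
  set.seed(41)
  for (i in 1:20) {
    q <- random_unit_quat()
    expect_equal(quat_multiply(c(1, 0, 0, 0), q), q, tolerance = 1e-12)
    expect_equal(quat_multiply(q, quat_conjugate(q)), c(1, 0, 0, 0),
                 tolerance = 1e-9)
  }
  two_z90 <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), pi / 2),
                           quat_from_axis_angle(c(0, 0, 1), pi / 2))
  expect_equal(two_z90, quat_from_axis_angle(c(0, 0, 1), pi),
               tolerance = 1e-12)
})

test_that("conjugation is an involution and negates the vector part", {
  expect_equal(quat_conjugate(c(1, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(quat_conjugate(c(0, 0, 0, 1)), c(0, 0, 0, -1))
  set.seed(42)
  q <- random_unit_quat()
  expect_equal(quat_conjugate(quat_conjugate(q)), q)
})

test_that("rotation matrix expansion is orthonormal and matches Rodrigues", {
  expect_equal(quat_to_rotation_matrix(c(1, 0, 0, 0)), diag(3))
  expect_equal(quat_to_rotation_matrix(c(0, 0, 0, 1)), diag(c(-1, -1, 1)))
  set.seed(43)
  for (i in 1:200) {
    q <- random_unit_quat()
    R <- quat_to_rotation_matrix(q)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    aa <- quat_axis_angle(q)
    v <- stats::rnorm(3)
    expect_equal(drop(R %*% v), rodrigues_rotate(v, aa$axis, aa$angle),
                 tolerance = 1e-9)
  }
})

test_that("matrix map is a homomorphism and respects the double cover", {
  set.seed(44)
  for (i in 1:50) {
    a <- random_unit_quat()
    b <- random_unit_quat()
    expect_equal(quat_to_rotation_matrix(quat_multiply(a, b)),
                 quat_to_rotation_matrix(a) %*% quat_to_rotation_matrix(b),
                 tolerance = 1e-9)
    expect_equal(quat_to_rotation_matrix(a), quat_to_rotation_matrix(-a),
                 tolerance = 1e-12)
  }
})

test_that("body-to-earth rotation inverts the frame map and preserves norms", {
  v <- stats::rnorm(3)
  expect_equal(rotate_body_to_earth(c(1, 0, 0, 0), v), v)

  q90 <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  out <- rotate_body_to_earth(q90, c(1, 0, 0))
  expect_equal(drop(t(quat_to_rotation_matrix(q90)) %*% c(1, 0, 0)), out,
               tolerance = 1e-12)
  expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-9)

  set.seed(45)
  for (i in 1:1000) {
    q <- random_unit_quat()
    v <- stats::rnorm(3)
    e <- rotate_body_to_earth(q, v)
    expect_equal(sqrt(sum(e^2)), sqrt(sum(v^2)), tolerance = 1e-9)
    # forward frame map followed by the inverse returns the input
    expect_equal(drop(quat_to_rotation_matrix(q) %*% e), v, tolerance = 1e-9)
  }
})

test_that("vectorized rotation agrees with the per-sample matrix route", {
  set.seed(46)
  qm <- t(replicate(25, random_unit_quat()))
  vm <- matrix(stats::rnorm(75), 25, 3)
  batch <- rotate_body_to_earth(qm, vm)
  for (i in 1:25) {
    expect_equal(batch[i, ], rotate_body_to_earth(qm[i, ], vm[i, ]),
                 tolerance = 1e-12)
  }
})

test_that("Euler conversion uses aerospace ZYX degrees and round-trips", {
  e0 <- quat_to_euler(c(1, 0, 0, 0))
  expect_equal(unlist(e0[c("yaw", "pitch", "roll")], use.names = FALSE),
               c(0, 0, 0))
  ey <- quat_to_euler(quat_from_axis_angle(c(0, 0, 1), pi / 2))
  expect_equal(ey$yaw, 90, tolerance = 1e-9)
  expect_equal(ey$pitch, 0, tolerance = 1e-9)
  expect_equal(ey$roll, 0, tolerance = 1e-9)

  set.seed(47)
  for (i in 1:50) {
    ang <- c(stats::runif(1, -179, 179), stats::runif(1, -85, 85),
             stats::runif(1, -179, 179))
    e <- quat_to_euler(quat_from_euler(ang[1], ang[2], ang[3]))
    expect_equal(c(e$yaw, e$pitch, e$roll), ang, tolerance = 1e-6)
    expect_false(e$gimbal_degenerate)
  }
})

test_that("gimbal-degenerate pitches are flagged", {
  q <- quat_from_axis_angle(c(0, 1, 0), pi / 2)
  expect_true(quat_to_euler(q)$gimbal_degenerate)
})

test_that("every operation returns unit-norm quaternions", {
  set.seed(48)
  for (i in 1:100) {
    a <- random_unit_quat()
    b <- random_unit_quat()
    expect_equal(sum(quat_multiply(a, b)^2), 1, tolerance = 1e-9)
    expect_equal(sum(quat_conjugate(a)^2), 1, tolerance = 1e-9)
    expect_equal(sum(quat_from_axis_angle(c(0, 0, 1),
                                          stats::runif(1, -10, 10))^2),
                 1, tolerance = 1e-9)
  }
})
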