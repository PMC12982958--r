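test_that("calibration offset maps the upright pose back to the baseline", {
  # forced by the contract: q_ref = q0 gives the identity correction
  q0 <- q_from_axis_angle(c(0, 1, 0), 12)
  qT <- compute_offset(q0, q0)
  expect_lt(q_rotation_angle(qT), 1e-9)

  # q0 = identity, q_ref a 30 deg Y rotation: correction is its inverse
  qref <- q_from_axis_angle(c(0, 1, 0), 30)
  qT <- compute_offset(quat(1, 0, 0, 0), qref)
  expect_lt(q_angle_between(qT, q_from_axis_angle(c(0, 1, 0), -30)), 1e-9)

  # property: apply_calibration(q_ref, q_T) == q0 for random pairs
  withr::with_seed(123, {
    for (i in 1:100) {
      q0 <- random_quat(); qref <- random_quat()
      qT <- compute_offset(q0, qref)
      expect_lt(q_angle_between(apply_calibration(qref, qT), q0), 1e-6)
    }
  })
  expect_error(compute_offset(quat(2, 0, 0, 0), quat(1, 0, 0, 0)), "unit")
})

test_that("relative knee rotation round-trips thigh and shank frames", {
  q <- q_from_axis_angle(c(1, 0.3, 2), 50)
  expect_lt(q_rotation_angle(knee_relative_rotation(q, q)), 1e-9)

  shank <- q_from_axis_angle(c(0, 0, 1), 15)
  rel40 <- q_from_axis_angle(c(0, 1, 0), 40)
  thigh <- q_multiply(shank, rel40)
  expect_lt(q_angle_between(knee_relative_rotation(thigh, shank), rel40), 1e-9)

  withr::with_seed(5, {
    qs <- random_quat(); qt <- random_quat()
    rel <- knee_relative_rotation(qt, qs)
    expect_lt(q_angle_between(q_multiply(qs, rel), qt), 1e-9)
  })
})

test_that("the Y Euler angle recovers pure-Y rotations in both conventions", {
  expect_equal(knee_angle_y(quat(1, 0, 0, 0), "included"), 180)
  expect_equal(knee_angle_y(q_from_axis_angle(c(0, 1, 0), 90), "included"), 90,
               tolerance = 1e-10)
  withr::with_seed(9, {
    theta <- runif(1000, 0, 180)
    err <- vapply(theta, function(a) {
      q <- q_from_axis_angle(c(0, 1, 0), a)
      abs(knee_angle_y(q, "flexion") - a)
    }, numeric(1))
    expect_lt(max(err), 1e-6)
  })
})

test_that("angle outputs are invariant to quaternion sign flips", {
  withr::with_seed(31, {
    for (i in 1:50) {
      q <- random_quat()
      d <- abs(knee_angle_y(q) - knee_angle_y(quat(-unclass(q))))
      expect_lt(d, 1e-9)
    }
  })
})

test_that("included/flexion conversion is an involution and angles stay bounded", {
  x <- c(0, 45, 90, 135, 180)
  expect_equal(flexion_to_included(included_to_flexion(x)), x)
  withr::with_seed(2, {
    for (i in 1:50) {
      a <- knee_angle_y(random_quat(), "included")
      expect_gte(a, 0); expect_lte(a, 180)
    }
  })
})

make_const_stream <- function(q, id, n = 1050, rate = 74) {
  Q <- matrix(unclass(q), n, 4, byrow = TRUE)
  sensor_stream(seq(0, by = 1 / rate, length.out = n), Q, id, rate)
}

test_that("constant upright streams calibrate to a 180 degree included angle", {
  m_t <- q_from_axis_angle(c(1, 1, 0), 25)
  m_s <- q_from_axis_angle(c(0, 1, 1), 18)
  flat <- list(thigh_BF = make_const_stream(quat(1, 0, 0, 0), "thigh_BF"),
               midshank = make_const_stream(quat(1, 0, 0, 0), "midshank"))
  upright <- list(thigh_BF = make_const_stream(m_t, "thigh_BF"),
                  midshank = make_const_stream(m_s, "midshank"))
  calib <- calibrate_sensors(flat, upright)
  ser <- stream_knee_angle(upright$thigh_BF, upright$midshank, calib)
  expect_lt(max(abs(ser$included_deg - 180)), 1e-6)
})

test_that("stream pairing tolerates sub-period shifts and rejects disjoint windows", {
  pr <- participant_profile("P1", "EG", error_bias = 3, seed = 4)
  sch <- test_schedule("pretest_squat", n = 3, rng_seed = 1)
  tr <- gen_trajectory(sch, pr, "pre", seed = 2)
  offs <- list(thigh_BF = q_from_axis_angle(c(1, 0, 2), 20),
               midshank = q_from_axis_angle(c(0, 1, 1), 10))
  imu <- angles_to_imu(tr, offs, orientation_noise_sd = 0, seed = 3)
  calib <- calibrate_sensors(imu$flat, imu$upright)
  base <- stream_knee_angle(imu$task$thigh_BF, imu$task$midshank, calib)

  shifted <- imu$task$midshank
  shifted$time_s <- shifted$time_s + 0.3 / 74   # < half a sample period
  again <- stream_knee_angle(imu$task$thigh_BF, shifted, calib)
  expect_equal(again$included_deg, base$included_deg)

  far <- imu$task$midshank
  far$time_s <- far$time_s + max(imu$task$thigh_BF$time_s) + 10
  expect_error(stream_knee_angle(imu$task$thigh_BF, far, calib), "overlap")
})

test_that("knee angles are recovered through calibration with mounting offsets", {
  pr <- participant_profile("P1", "CG", error_bias = -4, seed = 8)
  sch <- test_schedule("pretest_stretch", n = 4, rng_seed = 3)
  tr <- gen_trajectory(sch, pr, "pre", seed = 5)
  withr::with_seed(17, {
    ax <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
    offs <- list(thigh_BF = q_from_axis_angle(ax(), runif(1, 0, 30)),
                 midshank = q_from_axis_angle(ax(), runif(1, 0, 30)))
  })
  # noise-free: machine-precision recovery
  imu0 <- angles_to_imu(tr, offs, orientation_noise_sd = 0, seed = 6)
  cal0 <- calibrate_sensors(imu0$flat, imu0$upright)
  ser0 <- stream_knee_angle(imu0$task$thigh_BF, imu0$task$midshank, cal0)
  expect_lt(max(abs(ser0$included_deg - tr$included_deg)), 1e-6)
  # with orientation noise: sub-half-degree RMSE
  imu <- angles_to_imu(tr, offs, orientation_noise_sd = 0.25, seed = 7)
  cal <- calibrate_sensors(imu$flat, imu$upright)
  ser <- stream_knee_angle(imu$task$thigh_BF, imu$task$midshank, cal)
  expect_lt(sqrt(mean((ser$included_deg - tr$included_deg)^2)), 0.5)
})

test_that("sensor ingest validates norms and time ordering", {
  tq <- matrix(c(1, 0, 0, 0, 2, 0, 0, 0), 2, 4, byrow = TRUE)
  expect_error(sensor_stream(c(0, 1), tq, "midshank"), "unit-norm")
  uq <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0), 2, 4, byrow = TRUE)
  expect_error(sensor_stream(c(1, 1), uq, "midshank"), "increasing")
})
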