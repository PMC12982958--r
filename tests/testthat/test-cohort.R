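test_that("trajectory holds equal their targets when error vanishes", {
  pr <- participant_profile("P1", "CG", error_bias = 0, error_sd = 1e-9,
                            motor_noise_sd = 1e-9, seed = 1)
  for (kind in c("pretest_squat", "pretest_stretch")) {
    sch <- test_schedule(kind, rng_seed = 2)
    tr <- gen_trajectory(sch, pr, "pre", seed = 3)
    holds <- attr(tr, "holds")
    expect_equal(holds$aka_deg, holds$tka_deg, tolerance = 1e-6)
  }
})

test_that("the training effect attenuates post-test errors by the learning gain", {
  # law of the generator: gain 0.5 halves the expected |error|
  pr <- participant_profile("P1", "EG", error_bias = 6, error_sd = 3,
                            learning_gain = 0.5, seed = 4)
  sch <- test_schedule("pretest_squat", n = 10, rng_seed = 5)
  errs <- vapply(1:40, function(s) {
    pre <- attr(gen_trajectory(sch, pr, "pre", seed = 100 + s), "holds")
    post <- attr(gen_trajectory(sch, pr, "post", seed = 100 + s), "holds")
    c(mean(abs(pre$error_deg)), mean(abs(post$error_deg)))
  }, numeric(2))   # 40 x 10 = 400 movement draws per phase
  ratio <- mean(errs[2, ]) / mean(errs[1, ])
  expect_equal(ratio, 0.5, tolerance = 0.1)
})

test_that("hold errors follow the profile's bias and spread", {
  pr <- participant_profile("P1", "CG", error_bias = 5, error_sd = 3, seed = 6)
  sch <- test_schedule("pretest_squat", n = 10, rng_seed = 7)
  draws <- unlist(lapply(1:50, function(s) {
    attr(gen_trajectory(sch, pr, "pre", seed = 200 + s), "holds")$error_deg
  }))   # 500 draws
  se <- 3 / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 5), 3 * se)
  expect_lt(abs(sd(draws) - 3), 3 * 3 / sqrt(2 * (length(draws) - 1)))
})

test_that("the lognormal error option keeps the profile scale with heavier tails", {
  sch <- test_schedule("pretest_squat", n = 10, rng_seed = 51)
  draw <- function(dist) {
    pr <- participant_profile("P1", "CG", error_bias = 0, error_sd = 3,
                              error_dist = dist, seed = 52)
    unlist(lapply(1:60, function(s) {
      attr(gen_trajectory(sch, pr, "pre", seed = 300 + s), "holds")$error_deg
    }))
  }
  ln <- draw("lognormal")
  expect_lt(abs(mean(ln)), 3 * 3 / sqrt(length(ln)))
  expect_equal(sd(ln), 3, tolerance = 0.15)
  expect_gt(kurt <- mean((ln - mean(ln))^4) / sd(ln)^4, 3.5)  # heavy tail
})

test_that("trajectories and cohorts are seed-reproducible", {
  pr <- participant_profile("P1", "EG", error_bias = 2, seed = 8)
  sch <- test_schedule("pretest_stretch", rng_seed = 9)
  expect_identical(gen_trajectory(sch, pr, "pre", seed = 10),
                   gen_trajectory(sch, pr, "pre", seed = 10))
  a <- gen_cohort(n_eg = 2, n_cg = 2, include_imu = FALSE, seed = 11)
  b <- gen_cohort(n_eg = 2, n_cg = 2, include_imu = FALSE, seed = 11)
  expect_identical(a, b)
})

test_that("simulated calibration recordings honour the buffer contract", {
  pr <- participant_profile("P1", "CG", error_bias = 1, seed = 12)
  sch <- test_schedule("pretest_squat", n = 2, rng_seed = 13)
  tr <- gen_trajectory(sch, pr, "pre", seed = 14)
  offs <- list(thigh_BF = quat(1, 0, 0, 0), midshank = quat(1, 0, 0, 0))
  imu <- angles_to_imu(tr, offs, orientation_noise_sd = 0, seed = 15)
  # 14 s at 74 Hz supplies at least the 1000-sample buffer
  for (s in imu$flat) expect_gte(length(s$time_s), 1000)
  for (s in imu$upright) expect_gte(length(s$time_s), 1000)
  # zero offsets + zero noise: the stream pipeline reproduces the truth
  calib <- calibrate_sensors(imu$flat, imu$upright)
  ser <- stream_knee_angle(imu$task$thigh_BF, imu$task$midshank, calib)
  expect_lt(max(abs(ser$included_deg - tr$included_deg)), 1e-6)
})

test_that("the default cohort has the study's group structure", {
  co <- gen_cohort(include_imu = FALSE, seed = 16)
  expect_length(co$participants, 14)
  expect_equal(sum(co$groups == "EG"), 7)
  expect_equal(sum(co$groups == "CG"), 7)
  gains <- vapply(co$participants, `[[`, numeric(1), "learning_gain")
  expect_true(all(gains[co$groups == "EG"] == 0.8))
  expect_true(all(gains[co$groups == "CG"] == 0))
})

test_that("questionnaire tables stay within instrument bounds", {
  q <- gen_questionnaires(c("EG", "CG"), seed = 17)
  expect_true(all(q$imi$value >= 1 & q$imi$value <= 7))
  expect_true(all(q$ueq$value >= -3 & q$ueq$value <= 3))
  expect_identical(gen_questionnaires(c("EG", "CG"), seed = 17), q)
  # all-max responses aggregate to the scale ceiling
  qm <- gen_questionnaires(c("EG"), seed = 18, all_max = TRUE)
  sc <- score_ueq(split(qm$ueq$value, qm$ueq$dimension))
  expect_equal(unname(sc$dimensions), rep(3, 6))
})

test_that("noiseless synergy mixtures are exactly low-rank downstream", {
  sch <- fish_schedule(n_fish = 3, rng_seed = 19)
  ev <- simulate_events(sch, seed = 19)
  em <- gen_emg(ev, synergy_ground_truth(noise_sd = 0), fs = 250, seed = 20)
  fit <- fit_nmf(t(em$values), 3, restarts = 3, seed = 21)
  expect_gte(fit$vaf, 0.999)
})
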