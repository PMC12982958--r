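make_test_emg <- function(n_fish = 4, fs = 250, seed = 2) {
  sch <- fish_schedule(n_fish = n_fish, rng_seed = seed)
  ev <- simulate_events(sch, seed = seed)
  list(stream = gen_emg(ev, synergy_ground_truth(), fs = fs, snr_db = 20,
                        seed = seed),
       events = ev)
}

test_that("event-locked segmentation uses the stated windows", {
  ev <- data.frame(
    t = c(35, 12.0, 12.3, 12.6, 12.9, 13.2, 13.5, 13.8, 14.1, 14.5,
          20, 20.5),
    kind = c("fish_caught", rep("carrot_collected", 9),
             "carrot_collected", "carrot_collected"),
    trail = c(2L, rep(NA_integer_, 11)),
    group = c(NA_integer_, rep(1L, 9), 2L, 2L),
    ordinal = c(NA_integer_, 1:9, 1L, 2L),   # group 2 incomplete
    prompt = c("trail_150", rep("half_squat", 11)),
    stringsAsFactors = FALSE)
  tt <- seq(0, 40, by = 1 / 200)
  stream <- emg_stream(tt, matrix(abs(sin(tt * 3)) + 0.1,
                                  nrow = length(tt), ncol = 7), 200)
  segs <- segment_emg(stream, ev)
  wins <- lapply(segs, function(s) s$provenance$window)
  expect_length(segs, 2)          # 1 catch + 1 complete group; group 2 dropped
  expect_equal(wins[[1]], c(33, 35))      # 2 s before the catch
  expect_equal(wins[[2]], c(12.0, 14.5))  # first to ninth carrot

  # a fish missed yields no segment
  ev_miss <- ev[1, ]; ev_miss$kind <- "fish_missed"
  expect_length(segment_emg(stream, ev_miss), 0)

  # window outside the stream is skipped with a warning
  ev_out <- ev[1, ]; ev_out$t <- 1000
  expect_warning(segment_emg(stream, ev_out), "skipped")
})

test_that("preprocessing yields non-negative unit-variance channels", {
  em <- make_test_emg()
  segs <- segment_emg(em$stream, em$events)
  pp <- preprocess_emg(segs[[1]])
  expect_true(all(pp$matrix >= 0))
  expect_equal(unname(apply(pp$matrix, 1, sd)), rep(1, 7), tolerance = 1e-9)
  zero <- segs[[1]]
  zero$matrix["GL", ] <- 0
  expect_error(preprocess_emg(zero), "GL")
})

test_that("the band-pass stage matches the analytic Butterworth magnitudes", {
  fs <- 500
  tt <- seq(0, 6, by = 1 / fs)
  amp_ratio <- function(f, causal) {
    x <- sin(2 * pi * f * tt)
    y <- emg_bandpass(x, fs, causal = causal)
    mid <- seq(floor(length(y) * 0.3), floor(length(y) * 0.7))
    sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
  }
  # 50 Hz probe: single-pass low-pass bound 1/sqrt(1 + (50/30)^10) ~ 0.078
  expect_lt(amp_ratio(50, causal = TRUE), 1 / sqrt(1 + (50 / 30)^10) * 1.05)
  # 0.5 Hz probe: high-pass bound 1/sqrt(1 + (4/0.5)^10); the RMS window
  # retains a sliver of transient energy, hence the slack factor
  expect_lt(amp_ratio(0.5, causal = TRUE), 1 / sqrt(1 + (4 / 0.5)^10) * 1.5)
  # passband probe survives
  expect_gt(amp_ratio(15, causal = FALSE), 0.9)
  # zero-phase filtering squares the response: stricter stopband
  expect_lt(amp_ratio(50, causal = FALSE), amp_ratio(50, causal = TRUE))
})

test_that("filtering is linear before normalization", {
  withr::with_seed(14, {
    x <- rnorm(1000)
    y1 <- emg_bandpass(x, 250)
    y3 <- emg_bandpass(3 * x, 250)
    expect_equal(y3, 3 * y1, tolerance = 1e-10)
  })
})

test_that("EMG generation is seed-reproducible and event-locked", {
  a <- make_test_emg(seed = 5)
  b <- make_test_emg(seed = 5)
  expect_identical(a$stream$values, b$stream$values)
  # activation bursts concentrate near task events
  gt <- attr(a$stream, "ground_truth")
  anchors <- a$events$t[a$events$kind == "fish_caught"]
  tt <- a$stream$time_s
  near <- rowSums(vapply(anchors, function(t0) abs(tt - t0) < 2.2,
                         logical(length(tt)))) > 0
  expect_gt(mean(gt$H[, near]), 10 * mean(gt$H[, !near]))
})
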