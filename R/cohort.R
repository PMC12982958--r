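#' Participant profile for the synthetic cohort
#'
#' Encodes the generator's proprioceptive-error model for one
#' participant: a constant angle-reproduction bias plus zero-mean
#' Gaussian draw per movement, attenuated after training by
#' `learning_gain` (experimental group only, unless overridden).
#'
#' @param id participant label.
#' @param group `"EG"` (augmented auditory + visual feedback) or `"CG"`
#'   (visual only).
#' @param error_bias systematic reproduction bias in degrees.
#' @param error_sd per-movement error SD in degrees (> 0, default 3).
#' @param learning_gain fractional post-training error reduction in
#'   `[0, 1]`.
#' @param motor_noise_sd within-hold tremor SD in degrees (default 0.25).
#' @param error_dist shape of the per-movement error draw:
#'   `"gaussian"` (default) or `"lognormal"` (random-sign lognormal
#'   magnitude with the same scale; heavier tail, for sensitivity
#'   analysis of the non-normal case).
#' @param seed participant-level RNG seed.
#' @return object of class `participant_profile`.
#' @export
participant_profile <- function(id, group = c("EG", "CG"), error_bias = 0,
                                error_sd = 3, learning_gain = 0,
                                motor_noise_sd = 0.25,
                                error_dist = c("gaussian", "lognormal"),
                                seed = 1) {
  group <- match.arg(group)
  error_dist <- match.arg(error_dist)
  stopifnot(error_sd > 0, learning_gain >= 0, learning_gain <= 1)
  structure(list(id = id, group = group, error_bias = error_bias,
                 error_sd = error_sd, learning_gain = learning_gain,
                 motor_noise_sd = motor_noise_sd, error_dist = error_dist,
                 seed = as.integer(seed)),
            class = "participant_profile")
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Rest posture (included angle) per test family.
rest_angle_of <- function(schedule) {
  if (attr(schedule, "game") %in% c("pretest_stretch")) 135 else 180
}

#' Ground-truth knee trajectory for a scheduled test
#'
#' For each schedule entry the participant moves from rest to a held
#' angle equal to the target plus a proprioceptive error draw
#' (`bias + N(0, error_sd)`, attenuated by `learning_gain` when
#' `phase = "post"` and the profile belongs to the experimental group),
#' holds with small motor noise, and returns to rest. Transitions are
#' minimum-jerk (1 s). Realized hold angles are clamped to the
#' anatomically representable included range `[0, 180]`.
#'
#' @param schedule a test `protocol_schedule`.
#' @param profile a [participant_profile()].
#' @param phase `"pre"` or `"post"`.
#' @param rate sampling rate in Hz (default 74).
#' @param transition transition duration in seconds (default 1).
#' @param seed RNG seed (default: profile seed + phase offset).
#' @return a [knee_angle_series()] with attribute `holds`: data frame
#'   `entry`, `movement_class`, `tka_deg`, `convention`, `aka_deg`
#'   (ground-truth held angle in the schedule convention),
#'   `error_deg`.
#' @export
gen_trajectory <- function(schedule, profile, phase = c("pre", "post"),
                           rate = 74, transition = 1, seed = NULL) {
  phase <- match.arg(phase)
  if (is.null(seed)) seed <- profile$seed + ifelse(phase == "pre", 0L, 500000L)
  rest <- rest_angle_of(schedule)
  n_entry <- nrow(schedule)
  t_end <- max(schedule$end_s) + transition + 0.5
  tt <- seq(0, t_end, by = 1 / rate)
  with_seed(seed, {
    atten <- if (phase == "post") 1 - profile$learning_gain else 1
    eps <- if (identical(profile$error_dist, "lognormal")) {
      # random-sign lognormal magnitude rescaled to the profile SD
      sdlog <- 1
      mag <- stats::rlnorm(n_entry, log(profile$error_sd), sdlog)
      raw_sd <- profile$error_sd * exp(sdlog^2)   # sd of the signed draw
      sample(c(-1, 1), n_entry, replace = TRUE) * mag * profile$error_sd /
        raw_sd
    } else {
      stats::rnorm(n_entry, 0, profile$error_sd)
    }
    angle <- rep(rest, length(tt))
    holds <- vector("list", n_entry)
    for (i in seq_len(n_entry)) {
      s <- schedule$start_s[i]; e <- schedule$end_s[i]
      conv <- schedule$convention[i]
      target_inc <- if (conv == "flexion") 180 - schedule$target_deg[i] else schedule$target_deg[i]
      # squats: bias acts in the flexion direction; stretches: the bias
      # manifests as systematic under-extension (end-range undershoot),
      # so it enters the included scale with a negative sign
      bias_i <- if (conv == "included") -abs(profile$error_bias) else profile$error_bias
      err_i <- (bias_i + eps[i]) * atten
      # error acts in the target's convention; on the included scale a
      # flexion-convention error flips sign
      hold_inc <- target_inc + if (conv == "flexion") -err_i else err_i
      hold_inc <- min(max(hold_inc, 0), 180)
      sel_in <- tt >= s - transition & tt < s
      angle[sel_in] <- rest + (hold_inc - rest) * min_jerk((tt[sel_in] - (s - transition)) / transition)
      sel_hold <- tt >= s & tt <= e
      angle[sel_hold] <- hold_inc + stats::rnorm(sum(sel_hold), 0, profile$motor_noise_sd)
      sel_out <- tt > e & tt <= e + transition
      angle[sel_out] <- hold_inc + (rest - hold_inc) * min_jerk((tt[sel_out] - e) / transition)
      aka <- if (conv == "flexion") 180 - hold_inc else hold_inc
      holds[[i]] <- data.frame(
        entry = schedule$entry[i], movement_class = schedule$movement_class[i],
        tka_deg = schedule$target_deg[i], convention = conv,
        aka_deg = aka, error_deg = aka - schedule$target_deg[i],
        stringsAsFactors = FALSE)
    }
    series <- knee_angle_series(tt, pmin(pmax(angle, 0), 180))
    attr(series, "holds") <- do.call(rbind, holds)
    series
  })
}

# n random small rotations: axis uniform on the sphere, angle ~ N(0, sd_deg)
noise_quats <- function(n, sd_deg) {
  if (sd_deg <= 0) {
    return(matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4))
  }
  ax <- matrix(stats::rnorm(3 * n), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  half <- stats::rnorm(n, 0, sd_deg) * pi / 360
  cbind(cos(half), ax * sin(half))
}

#' Synthesize IMU quaternion streams from a knee trajectory
#'
#' Emits what the two leg sensors would record: a flat-surface
#' calibration buffer (sensors parallel, world-aligned), an
#' upright-stance buffer (each sensor rotated by its fixed mounting
#' offset), and the in-task streams in which the thigh-versus-shank
#' relative Y rotation equals the ground-truth flexion angle. Every
#' sample is additionally perturbed by a small random orientation error.
#'
#' @param truth a [knee_angle_series()] (ground-truth included angle).
#' @param mounting_offsets named list of unit [quat()]s for `thigh_BF`
#'   and `midshank`.
#' @param orientation_noise_sd per-sample orientation noise SD, degrees.
#' @param rate sampling rate in Hz (default 74).
#' @param calib_duration calibration recording length in s (default 14).
#' @param seed RNG seed.
#' @return list with `flat`, `upright` (named lists of
#'   [sensor_stream()]s) and `task` (thigh/shank streams), plus the
#'   input `truth`.
#' @export
angles_to_imu <- function(truth, mounting_offsets,
                          orientation_noise_sd = 0.25, rate = 74,
                          calib_duration = 14, seed = 1) {
  ids <- c("thigh_BF", "midshank")
  stopifnot(all(ids %in% names(mounting_offsets)))
  for (id in ids) {
    if (abs(q_norm(mounting_offsets[[id]]) - 1) > 1e-6) {
      stop("angles_to_imu: mounting offsets must be unit quaternions")
    }
  }
  with_seed(seed, {
    n_cal <- floor(calib_duration * rate) + 1
    t_cal <- seq(0, by = 1 / rate, length.out = n_cal)
    mk <- function(base_q, n, id, times) {
      Q <- qm_multiply(matrix(unclass(base_q), nrow = n, ncol = 4, byrow = TRUE),
                       noise_quats(n, orientation_noise_sd))
      sensor_stream(times, qm_normalize(Q), id, nominal_rate = rate)
    }
    flat <- list(
      thigh_BF = mk(quat(1, 0, 0, 0), n_cal, "thigh_BF", t_cal),
      midshank = mk(quat(1, 0, 0, 0), n_cal, "midshank", t_cal)
    )
    upright <- list(
      thigh_BF = mk(mounting_offsets$thigh_BF, n_cal, "thigh_BF", t_cal),
      midshank = mk(mounting_offsets$midshank, n_cal, "midshank", t_cal)
    )
    n <- nrow(truth)
    flex <- (180 - truth$included_deg) * pi / 180
    thigh_body <- cbind(cos(flex / 2), 0, sin(flex / 2), 0)
    Qt <- qm_multiply(thigh_body,
                      matrix(unclass(mounting_offsets$thigh_BF), n, 4, byrow = TRUE))
    Qt <- qm_multiply(Qt, noise_quats(n, orientation_noise_sd))
    Qs <- qm_multiply(matrix(unclass(mounting_offsets$midshank), n, 4, byrow = TRUE),
                      noise_quats(n, orientation_noise_sd))
    task <- list(
      thigh_BF = sensor_stream(truth$time_s, qm_normalize(Qt), "thigh_BF", rate),
      midshank = sensor_stream(truth$time_s, qm_normalize(Qs), "midshank", rate)
    )
    list(flat = flat, upright = upright, task = task, truth = truth)
  })
}

#' Generative ground truth for muscle synergies
#'
#' @param W_true muscles x k non-negative weight matrix; columns are
#'   normalized to unit norm. Default: 3 synergies with disjoint muscle
#'   supports (shank dorsiflexor/medial group, lateral shank group,
#'   thigh group).
#' @param burst_width Gaussian burst SD in seconds (default 0.25).
#' @param burst_offsets per-synergy burst-center offsets relative to
#'   each task event, seconds (default evenly spread over the 2 s
#'   pre-event window).
#' @param noise_sd additive noise SD (signal units).
#' @return object of class `synergy_ground_truth`.
#' @export
synergy_ground_truth <- function(W_true = NULL, burst_width = 0.25,
                                 burst_offsets = NULL, noise_sd = 0) {
  if (is.null(W_true)) {
    W_true <- matrix(0, 7, 3, dimnames = list(emg_muscles, NULL))
    W_true[c("TA", "GAM", "GLM"), 1] <- c(1, 0.8, 0.6)
    W_true[c("GL", "PL"), 2] <- c(1, 0.9)
    W_true[c("BF", "RF"), 3] <- c(1, 0.7)
  }
  W_true <- as.matrix(W_true)
  if (any(W_true < 0)) stop("synergy_ground_truth: W_true must be non-negative")
  k <- ncol(W_true)
  stopifnot(k >= 1, k <= nrow(W_true))
  W_true <- sweep(W_true, 2, sqrt(colSums(W_true^2)), "/")
  if (is.null(burst_offsets)) {
    burst_offsets <- -seq(1.6, 0.2, length.out = k)
  }
  stopifnot(length(burst_offsets) == k, burst_width > 0)
  structure(list(W_true = W_true, k = k, burst_width = burst_width,
                 burst_offsets = burst_offsets, noise_sd = noise_sd),
            class = "synergy_ground_truth")
}

#' Synthesize event-locked synergy-mixture EMG
#'
#' Builds activations `H` as non-negative Gaussian bursts locked to each
#' task event (one burst per synergy at its characteristic offset) and
#' mixes them as `E = W_true H + noise`, clipped at zero after mixing.
#'
#' @param events event-log data frame; rows with kind `fish_caught` or
#'   `carrot_collected` anchor the bursts.
#' @param truth a [synergy_ground_truth()].
#' @param fs sampling rate in Hz (default 1111).
#' @param duration stream length in s (default: covers all events + 1 s).
#' @param snr_db if given, overrides `truth$noise_sd` so that the noise
#'   RMS sits `snr_db` decibels below the clean-signal RMS.
#' @param seed RNG seed.
#' @return an [emg_stream()]; the realized `W_true`, `H` and noise SD
#'   are attached as attribute `ground_truth`.
#' @export
gen_emg <- function(events, truth = synergy_ground_truth(), fs = 1111,
                    duration = NULL, snr_db = NULL, seed = 1) {
  stopifnot(fs >= 100)
  anchor <- events$t[events$kind %in% c("fish_caught", "carrot_collected")]
  if (!length(anchor)) stop("gen_emg: no anchoring task events")
  if (is.null(duration)) duration <- max(anchor) + 1
  tt <- seq(0, duration, by = 1 / fs)
  k <- truth$k
  H <- matrix(0, k, length(tt))
  for (j in seq_len(k)) {
    for (a in anchor) {
      c0 <- a + truth$burst_offsets[j]
      H[j, ] <- H[j, ] + exp(-(tt - c0)^2 / (2 * truth$burst_width^2))
    }
  }
  clean <- truth$W_true %*% H
  noise_sd <- truth$noise_sd
  if (!is.null(snr_db)) {
    noise_sd <- sqrt(mean(clean^2)) * 10^(-snr_db / 20)
  }
  E <- with_seed(seed, {
    pmax(clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                        nrow(clean), ncol(clean)), 0)
  })
  out <- emg_stream(tt, t(E), fs)
  attr(out, "ground_truth") <- list(W_true = truth$W_true, H = H,
                                    noise_sd = noise_sd)
  out
}

#' Simulate game play events from a schedule
#'
#' Squat game: every carrot of every group is collected at its scheduled
#' time. Stretch game: each fish is caught `hold + 1` seconds after its
#' spawn with probability `catch_prob`, otherwise missed at escape.
#'
#' @param schedule a game `protocol_schedule` from [bunny_schedule()] or
#'   [fish_schedule()].
#' @param catch_prob probability a fish is caught (default 1).
#' @param hold,reach_delay catch hold and trail-reach latency, seconds.
#' @param seed RNG seed.
#' @return event-log data frame (`t`, `kind`, `trail`, `group`,
#'   `ordinal`, `prompt`).
#' @export
simulate_events <- function(schedule, catch_prob = 1, hold = 2,
                            reach_delay = 1, seed = 1) {
  game <- attr(schedule, "game")
  if (game == "bunny") {
    ct <- attr(schedule, "carrot_times")
    rows <- lapply(seq_len(nrow(schedule)), function(g) {
      data.frame(t = ct[[g]], kind = "carrot_collected", trail = NA_integer_,
                 group = g, ordinal = seq_along(ct[[g]]),
                 prompt = schedule$movement_class[g], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else if (game == "fish") {
    caught <- with_seed(seed, stats::runif(nrow(schedule)) < catch_prob)
    trail_map <- c(trail_90 = 0L, trail_120 = 1L, trail_150 = 2L, trail_180 = 3L)
    out <- data.frame(
      t = ifelse(caught, schedule$start_s + hold + reach_delay, schedule$end_s),
      kind = ifelse(caught, "fish_caught", "fish_missed"),
      trail = unname(trail_map[schedule$movement_class]),
      group = schedule$entry, ordinal = NA_integer_,
      prompt = schedule$movement_class, stringsAsFactors = FALSE)
  } else {
    stop("simulate_events: not a game schedule")
  }
  out[order(out$t), , drop = FALSE]
}

#' Synthetic questionnaire item tables
#'
#' Draws item-level responses with group-dependent means: intrinsic
#' motivation items on the 1-7 scale and user-experience items on the
#' -3..+3 scale.
#'
#' @param groups character vector of group labels per participant.
#' @param seed RNG seed.
#' @param all_max logical; emit the maximum rating everywhere (useful
#'   for checking aggregation bounds).
#' @return list of data frames `imi` (participant, group, subscale,
#'   item, value) and `ueq` (participant, group, dimension, item,
#'   value).
#' @export
gen_questionnaires <- function(groups, seed = 1, all_max = FALSE) {
  imi_items <- c(interest_enjoyment = 7, perceived_competence = 6,
                 perceived_choice = 5, pressure_tension = 5)
  imi_mean <- c(interest_enjoyment = 5, perceived_competence = 4.8,
                perceived_choice = 4.5, pressure_tension = 2.5)
  ueq_items <- c(attractiveness = 6, perspicuity = 4, efficiency = 4,
                 dependability = 4, stimulation = 4, novelty = 4)
  ueq_mean_eg <- c(attractiveness = 2.7, perspicuity = 2.8, efficiency = 2.1,
                   dependability = 2.5, stimulation = 2.5, novelty = 2.0)
  ueq_mean_cg <- ueq_mean_eg - 0.35
  with_seed(seed, {
    imi <- ueq <- list()
    for (p in seq_along(groups)) {
      bump <- if (groups[p] == "EG") 0.3 else 0
      for (sc in names(imi_items)) {
        v <- if (all_max) rep(7, imi_items[sc]) else {
          pmin(pmax(round(stats::rnorm(imi_items[sc], imi_mean[sc] + bump, 1)), 1), 7)
        }
        imi[[length(imi) + 1L]] <- data.frame(
          participant = p, group = groups[p], subscale = sc,
          item = seq_len(imi_items[sc]), value = v, stringsAsFactors = FALSE)
      }
      mu <- if (groups[p] == "EG") ueq_mean_eg else ueq_mean_cg
      for (dm in names(ueq_items)) {
        v <- if (all_max) rep(3, ueq_items[dm]) else {
          pmin(pmax(round(stats::rnorm(ueq_items[dm], mu[dm], 0.7)), -3), 3)
        }
        ueq[[length(ueq) + 1L]] <- data.frame(
          participant = p, group = groups[p], dimension = dm,
          item = seq_len(ueq_items[dm]), value = v, stringsAsFactors = FALSE)
      }
    }
    list(imi = do.call(rbind, imi), ueq = do.call(rbind, ueq))
  })
}

#' Generate a complete synthetic study cohort
#'
#' Builds participant profiles (experimental group with a training
#' effect, control group without), pre/post squat and stretch test
#' schedules, ground-truth trajectories, IMU streams with random
#' mounting offsets, game event logs, synergy-mixture EMG, and
#' questionnaire tables. All randomness derives from `seed`; the same
#' seed reproduces the dataset exactly.
#'
#' @param n_eg,n_cg group sizes (defaults 7 and 7).
#' @param effect fractional post-training error attenuation applied to
#'   the experimental group (default 0.8; control group 0).
#' @param bias_sd SD of the per-participant reproduction bias, degrees
#'   (default 10).
#' @param error_sd per-movement error SD, degrees (default 3).
#' @param motor_noise_sd within-hold tremor SD, degrees (default 0.25).
#' @param orientation_noise_sd IMU orientation noise SD, degrees
#'   (default 0.25).
#' @param max_offset_deg largest random sensor mounting offset, degrees
#'   (default 30).
#' @param seed master seed.
#' @param include_imu simulate IMU streams (default TRUE; when FALSE the
#'   ground-truth trajectories stand in as the measured series).
#' @param include_emg simulate game events and EMG (default FALSE; the
#'   kinematic pipeline does not need them).
#' @param emg_fs,emg_bunny_groups,emg_n_fish EMG simulation sizes
#'   (defaults 250 Hz, 3 squat groups, 4 fish) — a shortened session
#'   with the same event-locked structure as the full protocol.
#' @return object of class `cohort_dataset`: `participants` (profiles),
#'   `data` (per participant: schedules, truth series, IMU bundles,
#'   events, EMG), `questionnaires`, `seed`.
#' @export
gen_cohort <- function(n_eg = 7, n_cg = 7, effect = 0.8, bias_sd = 10,
                       error_sd = 3, motor_noise_sd = 0.25,
                       orientation_noise_sd = 0.25, max_offset_deg = 30,
                       seed = 1, include_imu = TRUE, include_emg = FALSE,
                       emg_fs = 250, emg_bunny_groups = 3, emg_n_fish = 4) {
  stopifnot(n_eg >= 1, n_cg >= 1)
  n <- n_eg + n_cg
  groups <- c(rep("EG", n_eg), rep("CG", n_cg))
  setup <- with_seed(seed, {
    list(bias = stats::rnorm(n, 0, bias_sd),
         pseed = sample.int(.Machine$integer.max - 1L, n))
  })
  participants <- lapply(seq_len(n), function(i) {
    participant_profile(
      id = sprintf("P%02d", i), group = groups[i],
      error_bias = setup$bias[i], error_sd = error_sd,
      learning_gain = if (groups[i] == "EG") effect else 0,
      motor_noise_sd = motor_noise_sd, seed = setup$pseed[i])
  })
  data <- lapply(participants, function(pr) {
    sq_sched <- test_schedule("pretest_squat", rng_seed = pr$seed + 1L)
    st_sched <- test_schedule("pretest_stretch", rng_seed = pr$seed + 2L)
    per_phase <- function(phase, off) {
      sq <- gen_trajectory(sq_sched, pr, phase, seed = pr$seed + off)
      st <- gen_trajectory(st_sched, pr, phase, seed = pr$seed + off + 1L)
      res <- list(squat_truth = sq, stretch_truth = st)
      if (include_imu) {
        offs <- with_seed(pr$seed + off + 2L, {
          rand_off <- function() {
            ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
            q_from_axis_angle(ax, stats::runif(1, 0, max_offset_deg))
          }
          list(thigh_BF = rand_off(), midshank = rand_off())
        })
        res$squat_imu <- angles_to_imu(sq, offs, orientation_noise_sd,
                                       seed = pr$seed + off + 3L)
        res$stretch_imu <- angles_to_imu(st, offs, orientation_noise_sd,
                                         seed = pr$seed + off + 4L)
        res$mounting_offsets <- offs
      }
      res
    }
    out <- list(profile = pr, squat_schedule = sq_sched,
                stretch_schedule = st_sched,
                pre = per_phase("pre", 10L), post = per_phase("post", 20L))
    if (include_emg) {
      bg <- bunny_schedule(groups = emg_bunny_groups, rng_seed = pr$seed + 30L)
      fg <- fish_schedule(n_fish = emg_n_fish, rng_seed = pr$seed + 31L)
      ev_b <- simulate_events(bg, seed = pr$seed + 32L)
      ev_f <- simulate_events(fg, seed = pr$seed + 33L)
      truth <- synergy_ground_truth()
      out$events_bunny <- ev_b
      out$events_fish <- ev_f
      out$emg_bunny <- gen_emg(ev_b, truth, fs = emg_fs, snr_db = 20,
                               seed = pr$seed + 34L)
      out$emg_fish <- gen_emg(ev_f, truth, fs = emg_fs, snr_db = 20,
                              seed = pr$seed + 35L)
      out$synergy_truth <- truth
    }
    out
  })
  names(data) <- vapply(participants, `[[`, character(1), "id")
  structure(
    list(participants = participants, data = data,
         questionnaires = gen_questionnaires(groups, seed = seed + 1L),
         groups = groups, seed = seed),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset: %d participants (%d EG, %d CG), seed %d>\n",
              length(x$participants), sum(x$groups == "EG"),
              sum(x$groups == "CG"), x$seed))
  invisible(x)
}
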