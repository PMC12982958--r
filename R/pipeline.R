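#' Study analysis configuration
#'
#' Every protocol constant of the study appears as a named, defaulted
#' key, so the default configuration runs the study protocol: 74 Hz
#' sensors, 14 s calibration recordings with a 1000-sample buffer, 12
#' squat groups of 9 carrots (2.5 s hold, 20 s gap), 12 fish (2 s catch,
#' 10 s escape), 10 + 10 test movements, |z| > 2.5 outlier rule,
#' alpha = .05, 85 % VAF threshold.
#'
#' @param ... overrides of the defaults listed below.
#' @return object of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = TRUE,
    # sensors & calibration
    rate = 74, calib_duration = 14, buffer_len = 1000,
    # game protocol
    bunny_groups = 12, carrots_per_group = 9, bunny_hold = 2.5, bunny_gap = 20,
    n_fish = 12, fish_hold = 2, fish_escape = 10,
    # tests
    test_n = 10, test_hold = 5,
    # analysis conventions
    ame_mode = "abs_of_mean", z_threshold = 2.5, outlier_scope = "pooled",
    alpha = 0.05, alternative = "greater",
    vaf_threshold = 85, nmf_restarts = 5, filter_causal = FALSE,
    # synthetic cohort
    n_eg = 7, n_cg = 7, effect = 0.8, bias_sd = 10, error_sd = 3,
    motor_noise_sd = 0.25, orientation_noise_sd = 0.25, max_offset_deg = 30,
    # synergy stage (scaled-down simulated session; see vignette)
    include_emg = FALSE, emg_fs = 250, emg_bunny_groups = 3, emg_n_fish = 4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("study_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$z_threshold > 0,
            cfg$vaf_threshold > 0, cfg$vaf_threshold < 100)
  structure(cfg, class = "study_config")
}

#' @rdname study_config
#' @param path YAML file with configuration keys.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

# Recover the measured knee-angle series of one test from its simulated
# IMU bundle: calibrate from the flat/upright buffers, then run the
# stream pipeline.
measure_series <- function(imu, buffer_len = 1000) {
  calib <- calibrate_sensors(imu$flat, imu$upright, buffer_len = buffer_len)
  stream_knee_angle(imu$task$thigh_BF, imu$task$midshank, calib)
}

# Kinematic stage: per-participant AME/IE metrics from a cohort_dataset.
cohort_kinematics <- function(cohort, config) {
  rows <- lapply(cohort$data, function(d) {
    get_series <- function(phase, fam) {
      ph <- d[[phase]]
      if (!is.null(ph[[paste0(fam, "_imu")]])) {
        measure_series(ph[[paste0(fam, "_imu")]], config$buffer_len)
      } else {
        ph[[paste0(fam, "_truth")]]
      }
    }
    seg <- function(phase) {
      rbind(segment_tests(get_series(phase, "squat"), d$squat_schedule),
            segment_tests(get_series(phase, "stretch"), d$stretch_schedule))
    }
    pm <- participant_metrics(seg("pre"), seg("post"), mode = config$ame_mode)
    cbind(data.frame(participant = d$profile$id, group = d$profile$group,
                     stringsAsFactors = FALSE), pm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Inference stage: z-score screening of the pooled IE values per
# movement group, then the EG-vs-CG rank test.
cohort_inference <- function(metrics, config) {
  res <- list()
  for (g in unique(metrics$movement_group)) {
    sub <- metrics[metrics$movement_group == g, ]
    scr <- if (config$outlier_scope == "pooled") {
      remove_outliers(sub$ie, config$z_threshold)
    } else {
      list(keep_mask = rep(TRUE, nrow(sub)), removed = numeric(0))
    }
    kept <- sub[scr$keep_mask, ]
    test <- mann_whitney(kept$ie[kept$group == "EG"],
                         kept$ie[kept$group == "CG"],
                         alternative = config$alternative)
    res[[g]] <- list(
      movement_group = g, test = test,
      n_removed = length(scr$removed),
      eg = describe(kept$ie[kept$group == "EG"]),
      cg = describe(kept$ie[kept$group == "CG"]),
      median_separation = stats::median(kept$ie[kept$group == "EG"]) -
        stats::median(kept$ie[kept$group == "CG"])
    )
  }
  res
}

# Synergy stage: per-segment VAF model selection, plus a per-task,
# per-group representative weight matrix and its EG-vs-CG consistency.
cohort_synergy <- function(cohort, config) {
  seg_rows <- list()
  pooled <- list()   # preprocessed matrices keyed by task label x group
  for (d in cohort$data) {
    if (is.null(d$emg_bunny)) next
    grp <- d$profile$group
    segsets <- list(
      list(stream = d$emg_bunny, events = d$events_bunny),
      list(stream = d$emg_fish, events = d$events_fish)
    )
    for (ss in segsets) {
      segs <- segment_emg(ss$stream, ss$events,
                          carrots_per_group = config$carrots_per_group)
      for (sg in segs) {
        pp <- preprocess_emg(sg, causal = config$filter_causal)
        sel <- select_synergy_number(pp, threshold = config$vaf_threshold,
                                     restarts = config$nmf_restarts,
                                     seed = cohort$seed + length(seg_rows))
        lab <- sg$provenance$label
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          participant = d$profile$id, group = grp, task = lab,
          k = sel$k, vaf = sel$vaf_by_k[sel$k], stringsAsFactors = FALSE)
        key <- paste(lab, grp, sep = "|")
        pooled[[key]] <- cbind(pooled[[key]], pp$matrix)
      }
    }
  }
  if (!length(seg_rows)) return(NULL)
  seg_df <- do.call(rbind, seg_rows)
  tasks <- unique(seg_df$task)
  consistency <- lapply(tasks, function(lab) {
    ks <- seg_df$k[seg_df$task == lab]
    k_rep <- max(1L, as.integer(round(stats::median(ks))))
    W <- lapply(c("EG", "CG"), function(grp) {
      M <- pooled[[paste(lab, grp, sep = "|")]]
      if (is.null(M)) return(NULL)
      fit_nmf(M, k_rep, restarts = config$nmf_restarts,
              seed = cohort$seed + 77L)$W
    })
    if (is.null(W[[1]]) || is.null(W[[2]])) return(NULL)
    m <- match_synergies(W[[1]], W[[2]])
    list(task = lab, k = k_rep, W_eg = W[[1]], W_cg = W[[2]],
         mean_cosine = m$mean_cosine, pairs = m$pairs)
  })
  consistency <- Filter(Negate(is.null), consistency)
  list(segments = seg_df,
       k_tally = as.data.frame(table(k = seg_df$k), stringsAsFactors = FALSE),
       consistency = consistency)
}

# Questionnaire stage: subscale/dimension scores per participant, then
# group means.
cohort_questionnaires <- function(q) {
  imi_scores <- do.call(rbind, lapply(split(q$imi, q$imi$participant), function(pi) {
    sc <- score_imi(split(pi$value, pi$subscale), mode = "sum")
    cbind(data.frame(participant = pi$participant[1], group = pi$group[1],
                     stringsAsFactors = FALSE), as.data.frame(t(sc)))
  }))
  ueq_scores <- do.call(rbind, lapply(split(q$ueq, q$ueq$participant), function(pi) {
    sc <- score_ueq(split(pi$value, pi$dimension))
    cbind(data.frame(participant = pi$participant[1], group = pi$group[1],
                     stringsAsFactors = FALSE),
          as.data.frame(t(sc$dimensions)),
          data.frame(pragmatic = sc$pragmatic, hedonic = sc$hedonic))
  }))
  group_mean <- function(df) {
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    num <- setdiff(num, "participant")
    do.call(rbind, lapply(split(df, df$group), function(s) {
      cbind(data.frame(group = s$group[1], stringsAsFactors = FALSE),
            as.data.frame(t(colMeans(s[num]))))
    }))
  }
  list(imi = imi_scores, ueq = ueq_scores,
       imi_group_means = group_mean(imi_scores),
       ueq_group_means = group_mean(ueq_scores))
}

#' Run the full study analysis
#'
#' Simulates (or accepts) a cohort and executes the complete analysis:
#' sensor calibration, knee-angle recovery, test segmentation, AME/IE
#' metrics, z-score outlier screening, EG-vs-CG Mann-Whitney tests per
#' movement group, optional EMG synergy extraction with VAF model
#' selection and cross-group weight matching, and questionnaire scoring.
#'
#' @param config a [study_config()].
#' @param cohort optional pre-built [gen_cohort()] dataset (overrides
#'   `config$simulate`).
#' @param out_dir optional directory for the JSON report and CSV tables.
#' @return object of class `study_report`.
#' @export
run_pipeline <- function(config = study_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(cohort)) {
    if (!config$simulate) stop("run_pipeline: no cohort given and simulate = FALSE")
    cohort <- gen_cohort(
      n_eg = config$n_eg, n_cg = config$n_cg, effect = config$effect,
      bias_sd = config$bias_sd, error_sd = config$error_sd,
      motor_noise_sd = config$motor_noise_sd,
      orientation_noise_sd = config$orientation_noise_sd,
      max_offset_deg = config$max_offset_deg, seed = config$seed,
      include_emg = config$include_emg, emg_fs = config$emg_fs,
      emg_bunny_groups = config$emg_bunny_groups,
      emg_n_fish = config$emg_n_fish)
  }
  metrics <- cohort_kinematics(cohort, config)
  inference <- cohort_inference(metrics, config)
  synergy <- cohort_synergy(cohort, config)
  questionnaires <- cohort_questionnaires(cohort$questionnaires)
  report <- structure(
    list(metrics = metrics, inference = inference, synergy = synergy,
         questionnaires = questionnaires, config = unclass(config),
         n_participants = length(cohort$participants)),
    class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d participants>\n", x$n_participants))
  for (g in names(x$inference)) {
    r <- x$inference[[g]]
    cat(sprintf("  %s test: U = %.1f, one-sided p = %.4f, EG median IE = %.2f, CG = %.2f\n",
                g, r$test$U, r$test$p_one_sided_greater,
                r$eg$median, r$cg$median))
  }
  if (!is.null(x$synergy)) {
    cat(sprintf("  synergy: %d segments, selected k: %s\n",
                nrow(x$synergy$segments),
                paste(sort(unique(x$synergy$segments$k)), collapse = ",")))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' `report.json` (machine-readable) plus `metrics.csv` and
#' `rank_tests.csv` (human-readable tables).
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  rt <- do.call(rbind, lapply(report$inference, function(r) {
    data.frame(movement_group = r$movement_group, U = r$test$U,
               p_one_sided = r$test$p_one_sided_greater,
               p_two_sided = r$test$p_two_sided, method = r$test$method,
               eg_median = r$eg$median, eg_q1 = r$eg$q1, eg_q3 = r$eg$q3,
               cg_median = r$cg$median, cg_q1 = r$cg$q1, cg_q3 = r$cg$q3,
               outliers_removed = r$n_removed)
  }))
  utils::write.csv(rt, file.path(dir, "rank_tests.csv"), row.names = FALSE)
  json <- list(
    n_participants = report$n_participants,
    rank_tests = rt,
    synergy_k_tally = report$synergy$k_tally,
    synergy_consistency = if (!is.null(report$synergy)) {
      lapply(report$synergy$consistency, function(cc) {
        list(task = cc$task, k = cc$k, mean_cosine = cc$mean_cosine)
      })
    },
    imi_group_means = report$questionnaires$imi_group_means,
    ueq_group_means = report$questionnaires$ueq_group_means,
    config = report$config)
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", null = "null", na = "null"),
             file.path(dir, "report.json"))
  invisible(dir)
}

#' Write a simulated cohort's raw files
#'
#' Emits, per participant, the sensor CSVs, event JSONL and EMG CSV the
#' pipeline ingests, plus a manifest JSON with all seeds; regenerating
#' with the manifest's master seed reproduces the files byte-for-byte.
#'
#' @param cohort a [gen_cohort()] dataset.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$data)) {
    d <- cohort$data[[id]]
    pdir <- file.path(dir, id)
    dir.create(pdir, showWarnings = FALSE)
    for (phase in c("pre", "post")) {
      for (fam in c("squat", "stretch")) {
        imu <- d[[phase]][[paste0(fam, "_imu")]]
        if (is.null(imu)) next
        for (part in c("flat", "upright", "task")) {
          for (sid in names(imu[[part]])) {
            write_sensor_csv(imu[[part]][[sid]],
                             file.path(pdir, sprintf("%s_%s_%s_%s.csv",
                                                     phase, fam, part, sid)))
          }
        }
      }
    }
    if (!is.null(d$events_bunny)) {
      write_events(d$events_bunny, file.path(pdir, "events_bunny.jsonl"))
      write_events(d$events_fish, file.path(pdir, "events_fish.jsonl"))
      write_emg_csv(d$emg_bunny, file.path(pdir, "emg_bunny.csv"))
      write_emg_csv(d$emg_fish, file.path(pdir, "emg_fish.csv"))
    }
  }
  manifest <- list(
    seed = cohort$seed, groups = cohort$groups,
    participants = lapply(cohort$participants, function(p) {
      list(id = p$id, group = p$group, seed = p$seed,
           error_bias = p$error_bias, error_sd = p$error_sd,
           learning_gain = p$learning_gain)
    }))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
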