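#' Signed joint-position error of one movement
#'
#' `error = AKA - TKA`: actual minus target knee angle, both in the same
#' angle convention.
#'
#' @param aka actual knee angle, degrees.
#' @param tka target knee angle, degrees.
#' @param convention convention both angles are expressed in; recorded
#'   only to guard against mixing.
#' @export
movement_error <- function(aka, tka, convention = c("included", "flexion")) {
  convention <- match.arg(convention)
  aka - tka
}

#' Segment a knee-angle series into test movements
#'
#' One segment per schedule entry. The actual knee angle (AKA) of a
#' movement is the mean angle over the central fraction of the hold
#' window (default 60 %, excluding the transitions into and out of the
#' hold); the signed error is `AKA - TKA` in the schedule's convention.
#'
#' @param series a [knee_angle_series()].
#' @param schedule a `protocol_schedule` whose windows lie within the
#'   series time span.
#' @param central_frac fraction of each hold used for the AKA mean.
#' @return data frame of class `movement_segments`: `entry`,
#'   `movement_class`, `start_s`, `end_s`, `tka_deg`, `aka_deg`,
#'   `error_deg`, `convention`, `n_samples`. Windows with fewer than 3
#'   samples are dropped with a warning.
#' @export
segment_tests <- function(series, schedule, central_frac = 0.6) {
  stopifnot(inherits(series, "knee_angle_series"), central_frac > 0,
            central_frac <= 1)
  if (min(schedule$start_s) < min(series$time_s) - 1e-9 ||
      max(schedule$end_s) > max(series$time_s) + 1e-9) {
    stop("segment_tests: schedule window outside the series span")
  }
  conv <- schedule$convention[1]
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    mid <- (schedule$start_s[i] + schedule$end_s[i]) / 2
    halfwin <- (schedule$end_s[i] - schedule$start_s[i]) * central_frac / 2
    sel <- series$time_s >= mid - halfwin & series$time_s <= mid + halfwin
    if (sum(sel) < 3) return(NULL)
    aka_inc <- mean(series$included_deg[sel])
    aka <- if (conv == "flexion") included_to_flexion(aka_inc) else aka_inc
    data.frame(
      entry = schedule$entry[i],
      movement_class = schedule$movement_class[i],
      start_s = schedule$start_s[i], end_s = schedule$end_s[i],
      tka_deg = schedule$target_deg[i], aka_deg = aka,
      error_deg = movement_error(aka, schedule$target_deg[i], conv),
      convention = conv, n_samples = sum(sel),
      stringsAsFactors = FALSE
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("segment_tests: dropped %d window(s) with < 3 samples", dropped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("segment_tests: no usable segments")
  class(out) <- c("movement_segments", "data.frame")
  out
}

#' Average mean error of a movement group
#'
#' Default is the absolute value of the mean signed error,
#' `|sum(AE) / n|`; `mode = "mean_of_abs"` gives `mean(|AE|)` instead
#' (the two differ whenever positive and negative errors cancel).
#'
#' @param errors signed errors in degrees (non-empty).
#' @param mode `"abs_of_mean"` (default) or `"mean_of_abs"`.
#' @return AME in degrees (non-negative).
#' @export
ame <- function(errors, mode = c("abs_of_mean", "mean_of_abs")) {
  mode <- match.arg(mode)
  if (!length(errors)) stop("ame: empty error list")
  if (mode == "abs_of_mean") abs(mean(errors)) else mean(abs(errors))
}

#' Improvement of error between pre- and post-test
#'
#' `IE = AME_pre - AME_post`; positive values indicate improvement.
#'
#' @param ame_pre,ame_post non-negative AME values in degrees.
#' @export
ie <- function(ame_pre, ame_post) {
  stopifnot(all(ame_pre >= 0), all(ame_post >= 0))
  ame_pre - ame_post
}

#' Z-score outlier screening
#'
#' Single pass: z-scores are computed once on the full list (sample SD
#' by default) and values with `|z| > threshold` are removed. A
#' zero-variance list passes through untouched.
#'
#' @param values numeric vector.
#' @param z_threshold cut-off on `|z|` (default 2.5).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return list with `kept`, `removed`, and logical `keep_mask`.
#' @export
remove_outliers <- function(values, z_threshold = 2.5,
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n <- length(values)
  if (n < 2) {
    return(list(kept = values, removed = numeric(0), keep_mask = rep(TRUE, n)))
  }
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0) {
    return(list(kept = values, removed = numeric(0), keep_mask = rep(TRUE, n)))
  }
  z <- (values - mean(values)) / s
  keep <- abs(z) <= z_threshold
  list(kept = values[keep], removed = values[!keep], keep_mask = keep)
}

# Movement classes forming the two test movement groups.
movement_group_of <- function(movement_class) {
  ifelse(movement_class %in% c("half_squat", "deep_squat"), "squat",
  ifelse(movement_class %in% c("stretch_45", "stretch_0"), "stretch",
         movement_class))
}

#' Per-participant AME and IE from segmented pre/post tests
#'
#' Aggregates segments into the two test movement groups (squat and
#' stretch) and computes AME for each phase and their difference IE.
#'
#' @param pre,post `movement_segments` from [segment_tests()] for the
#'   pre- and post-test of one participant (both test families may be
#'   concatenated with `rbind`).
#' @param mode AME aggregation mode, see [ame()].
#' @return data frame with one row per movement group: `movement_group`,
#'   `ame_pre`, `ame_post`, `ie`, `n_pre`, `n_post`.
#' @export
participant_metrics <- function(pre, post, mode = c("abs_of_mean", "mean_of_abs")) {
  mode <- match.arg(mode)
  groups <- sort(unique(movement_group_of(c(pre$movement_class, post$movement_class))))
  out <- lapply(groups, function(g) {
    e_pre <- pre$error_deg[movement_group_of(pre$movement_class) == g]
    e_post <- post$error_deg[movement_group_of(post$movement_class) == g]
    if (!length(e_pre) || !length(e_post)) return(NULL)
    a_pre <- ame(e_pre, mode); a_post <- ame(e_post, mode)
    data.frame(movement_group = g, ame_pre = a_pre, ame_post = a_post,
               ie = ie(a_pre, a_post),
               n_pre = length(e_pre), n_post = length(e_post),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
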