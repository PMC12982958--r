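# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards. seed = NULL leaves
# the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

new_schedule <- function(df, game) {
  structure(df, game = game, class = c("protocol_schedule", "data.frame"))
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule %s: %d entries, %.1f s total>\n",
              attr(x, "game"), nrow(x), max(x$end_s)))
  NextMethod()
}

#' Squat-game (closed kinetic chain) round schedule
#'
#' One round prompts `groups` squats. Each group presents
#' `carrots_per_group` collectibles during a `hold`-second squat hold and
#' is followed by a `gap`-second stand-up rest. The squat depth of each
#' group (half squat, target flexion 90 deg; deep squat, target flexion
#' 130 deg) is an independent fair coin draw.
#'
#' @param groups number of carrot groups per round (default 12).
#' @param carrots_per_group collectibles per group (default 9).
#' @param hold squat hold duration in seconds (default 2.5).
#' @param gap rest between groups in seconds (default 20).
#' @param rng_seed integer seed for the depth randomization.
#' @return a `protocol_schedule` with columns `start_s`, `end_s`,
#'   `target_deg`, `convention`, `movement_class`, `entry`; carrot times
#'   per group in `attr(, "carrot_times")`.
#' @export
bunny_schedule <- function(groups = 12, carrots_per_group = 9, hold = 2.5,
                           gap = 20, rng_seed = NULL) {
  if (groups < 1 || carrots_per_group < 1 || hold <= 0 || gap < 0) {
    stop("bunny_schedule: counts must be positive")
  }
  deep <- with_seed(rng_seed, stats::runif(groups) < 0.5)
  start <- (seq_len(groups) - 1) * (hold + gap)
  df <- data.frame(
    start_s = start, end_s = start + hold,
    target_deg = ifelse(deep, 130, 90), convention = "flexion",
    movement_class = ifelse(deep, "deep_squat", "half_squat"),
    entry = seq_len(groups)
  )
  sched <- new_schedule(df, "bunny")
  attr(sched, "carrot_times") <- lapply(seq_len(groups), function(g) {
    start[g] + seq(0, hold, length.out = carrots_per_group)
  })
  sched
}

#' Stretch-game (open kinetic chain) round schedule
#'
#' `n_fish` fish spawn one at a time on one of four trails corresponding
#' to included knee angles 90, 120, 150, 180 deg (lowest to highest). A
#' fish is caught if the hook holds its trail for `hold` seconds and
#' escapes after `escape` seconds. Spawns are spaced so windows never
#' overlap.
#'
#' @param n_fish fish per round (default 12).
#' @param hold catch hold in seconds (default 2).
#' @param escape escape timeout in seconds (default 10).
#' @param spawn_interval seconds between spawns (default `escape + 2`).
#' @param rng_seed integer seed for trail sampling.
#' @return a `protocol_schedule`; `target_deg` is the included trail
#'   angle, `movement_class` is `trail_<angle>`.
#' @export
fish_schedule <- function(n_fish = 12, hold = 2, escape = 10,
                          spawn_interval = escape + 2, rng_seed = NULL) {
  if (n_fish < 1 || hold <= 0 || escape <= hold) {
    stop("fish_schedule: invalid parameters")
  }
  trail_angles <- c(90, 120, 150, 180)
  ang <- with_seed(rng_seed, sample(trail_angles, n_fish, replace = TRUE))
  start <- (seq_len(n_fish) - 1) * spawn_interval
  new_schedule(data.frame(
    start_s = start, end_s = start + escape,
    target_deg = ang, convention = "included",
    movement_class = paste0("trail_", ang),
    entry = seq_len(n_fish)
  ), "fish")
}

#' Pre/post test schedule
#'
#' Ten prompted movements held for about 5 s each, alternating randomly
#' between the two targets of the movement family: squats (target flexion
#' 90 or 130 deg) or seated stretches (target included 135 or 180 deg,
#' i.e. half and full stretch).
#'
#' @param kind `"pretest_squat"` or `"pretest_stretch"`.
#' @param n number of movements (default 10).
#' @param hold hold duration in seconds (default 5).
#' @param rest rest between movements in seconds (default 3).
#' @param rng_seed integer seed for target order.
#' @return a `protocol_schedule`.
#' @export
test_schedule <- function(kind = c("pretest_squat", "pretest_stretch"),
                          n = 10, hold = 5, rest = 3, rng_seed = NULL) {
  kind <- match.arg(kind)
  if (n < 1) stop("test_schedule: n must be >= 1")
  classes <- if (kind == "pretest_squat") {
    data.frame(movement_class = c("half_squat", "deep_squat"),
               target_deg = c(90, 130), convention = "flexion")
  } else {
    data.frame(movement_class = c("stretch_45", "stretch_0"),
               target_deg = c(135, 180), convention = "included")
  }
  pick <- with_seed(rng_seed, {
    base <- rep(1:2, length.out = n)
    sample(base, n)
  })
  cycle <- hold + rest + 2   # 1 s transition into and out of the hold
  start <- (seq_len(n) - 1) * cycle + 1
  new_schedule(data.frame(
    start_s = start, end_s = start + hold,
    target_deg = classes$target_deg[pick],
    convention = classes$convention[1],
    movement_class = classes$movement_class[pick],
    entry = seq_len(n)
  ), kind)
}

#' Map a knee angle to a vertical screen position
#'
#' Squat game: position rises with flexion (the deeper the squat, the
#' higher the jump), linear from flexion 0 (position 0) to 180 (position
#' 1). Stretch game: position rises with the included angle, with the
#' four trail angles 90, 120, 150, 180 deg landing exactly on positions
#' 0, 1/3, 2/3, 1.
#'
#' @param included_deg included knee angle(s), degrees.
#' @param game `"bunny"` or `"fish"`.
#' @return position(s) in `[0, 1]`; out-of-range angles are clamped with
#'   a warning.
#' @export
angle_to_position <- function(included_deg, game = c("bunny", "fish")) {
  game <- match.arg(game)
  if (any(included_deg < 0 | included_deg > 180)) {
    warning("angle_to_position: angle outside [0, 180] clamped")
    included_deg <- pmin(pmax(included_deg, 0), 180)
  }
  pos <- if (game == "bunny") (180 - included_deg) / 180
         else (included_deg - 90) / 90
  pmin(pmax(pos, 0), 1)
}

#' Snap a screen position to the nearest fish trail
#'
#' Trails sit at positions 0, 1/3, 2/3, 1 (indices 0-3). Exact midpoints
#' round to the lower trail.
#'
#' @param position numeric in `[0, 1]`.
#' @return integer trail index in `0:3`.
#' @export
quantize_trail <- function(position) {
  stopifnot(all(position >= 0 & position <= 1))
  x <- position * 3
  idx <- floor(x + 0.5)
  tie <- abs(x - floor(x) - 0.5) < 1e-9
  idx[tie] <- floor(x[tie])
  as.integer(pmin(pmax(idx, 0), 3))
}

#' Sonification mapping for auditory feedback
#'
#' Maps a vertical game position to one short percussive stimulus:
#' amplitude scales linearly from silence (position 0) to the maximum
#' non-clipping volume (position 1), and the pitch index ascends a fixed
#' monotone semitone ladder. With feedback disabled (control group) a
#' silence marker is returned.
#'
#' @param position numeric in `[0, 1]`.
#' @param enabled logical; `FALSE` yields the silence marker.
#' @param n_steps pitch ladder size in semitones (default 25, two
#'   chromatic octaves).
#' @param duration stimulus duration in seconds, within `[0.1, 0.2]`.
#' @return a list with `position`, `pitch_index`, `amplitude`,
#'   `duration`, `silent`.
#' @export
sonify <- function(position, enabled = TRUE, n_steps = 25, duration = 0.15) {
  stopifnot(position >= 0, position <= 1,
            duration >= 0.1, duration <= 0.2, n_steps >= 2)
  if (!enabled) {
    return(list(position = position, pitch_index = NA_integer_,
                amplitude = 0, duration = duration, silent = TRUE))
  }
  list(
    position = position,
    pitch_index = as.integer(min(floor(position * (n_steps - 1)), n_steps - 1)),
    amplitude = position,
    duration = duration,
    silent = FALSE
  )
}

#' Prompt events of a schedule
#'
#' One `prompt_shown` event per schedule entry, in the JSONL event-log
#' dialect used throughout the package.
#'
#' @param schedule a `protocol_schedule`.
#' @return data frame with columns `t`, `kind`, `trail`, `group`,
#'   `ordinal`, `prompt`.
#' @export
schedule_prompts <- function(schedule) {
  trail_map <- c(trail_90 = 0L, trail_120 = 1L, trail_150 = 2L, trail_180 = 3L)
  data.frame(
    t = schedule$start_s,
    kind = "prompt_shown",
    trail = unname(trail_map[schedule$movement_class]),
    group = schedule$entry,
    ordinal = NA_integer_,
    prompt = schedule$movement_class,
    stringsAsFactors = FALSE
  )
}
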