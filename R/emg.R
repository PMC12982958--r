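#' Fixed muscle montage of the EMG recordings
#'
#' Tibialis anterior, gastrocnemius medialis, gluteus medius,
#' gastrocnemius lateralis, peroneus longus, biceps femoris, rectus
#' femoris.
#' @export
emg_muscles <- c("TA", "GAM", "GLM", "GL", "PL", "BF", "RF")

#' Multi-channel EMG stream
#'
#' @param time_s strictly increasing sample times (s).
#' @param values n x 7 numeric matrix, columns in [emg_muscles] order.
#' @param fs sampling rate in Hz.
#' @return object of class `emg_stream`.
#' @export
emg_stream <- function(time_s, values, fs) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(emg_muscles),
            nrow(values) == length(time_s), fs > 0)
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("emg_stream: time must be strictly increasing")
  }
  colnames(values) <- emg_muscles
  structure(list(time_s = as.numeric(time_s), values = values, fs = fs),
            class = "emg_stream")
}

#' @export
print.emg_stream <- function(x, ...) {
  cat(sprintf("<emg_stream: %d channels x %d samples @ %g Hz>\n",
              ncol(x$values), nrow(x$values), x$fs))
  invisible(x)
}

new_emg_segment <- function(mat, fs, provenance) {
  structure(list(matrix = mat, fs = fs, provenance = provenance),
            class = "emg_segment")
}

#' Event-locked EMG segmentation
#'
#' Stretch game: each `fish_caught` event yields the window from 2 s
#' before the catch up to the event. Squat game: a complete carrot group
#' (ordinals 1..9 all collected) yields the window from the first to the
#' ninth carrot. Misses and incomplete groups yield no segment; windows
#' falling outside the stream are skipped with a warning.
#'
#' @param stream an [emg_stream()].
#' @param events event-log data frame (`t`, `kind`, `trail`, `group`,
#'   `ordinal`, `prompt`), as produced by [schedule_prompts()] or the
#'   cohort simulator.
#' @param pre_window seconds before a catch (default 2).
#' @param carrots_per_group group completeness requirement (default 9).
#' @return list of `emg_segment` objects (muscles x samples matrices with
#'   `fs` and provenance).
#' @export
segment_emg <- function(stream, events, pre_window = 2, carrots_per_group = 9) {
  stopifnot(inherits(stream, "emg_stream"))
  windows <- list()
  fish <- events[events$kind == "fish_caught", , drop = FALSE]
  for (i in seq_len(nrow(fish))) {
    windows[[length(windows) + 1L]] <- list(
      from = fish$t[i] - pre_window, to = fish$t[i],
      label = if (!is.null(fish$prompt)) fish$prompt[i] else "fish",
      event = sprintf("fish_caught@%.3f", fish$t[i]))
  }
  carrots <- events[events$kind == "carrot_collected", , drop = FALSE]
  if (nrow(carrots)) {
    for (g in unique(carrots$group)) {
      cg <- carrots[carrots$group == g, , drop = FALSE]
      if (!all(seq_len(carrots_per_group) %in% cg$ordinal)) next
      windows[[length(windows) + 1L]] <- list(
        from = min(cg$t[cg$ordinal == 1]),
        to = max(cg$t[cg$ordinal == carrots_per_group]),
        label = if (!is.null(cg$prompt)) cg$prompt[1] else "squat",
        event = sprintf("carrot_group_%d", g))
    }
  }
  segs <- list()
  skipped <- 0L
  for (w in windows) {
    sel <- stream$time_s >= w$from - 1e-9 & stream$time_s <= w$to + 1e-9
    if (w$from < min(stream$time_s) - 1e-9 || w$to > max(stream$time_s) + 1e-9 ||
        sum(sel) < 2) {
      skipped <- skipped + 1L
      next
    }
    segs[[length(segs) + 1L]] <- new_emg_segment(
      t(stream$values[sel, , drop = FALSE]), stream$fs,
      list(label = w$label, event = w$event, window = c(w$from, w$to)))
  }
  if (skipped > 0) {
    warning(sprintf("segment_emg: skipped %d window(s) outside the stream", skipped))
  }
  segs
}

#' Butterworth band-limiting stage of the EMG chain
#'
#' Fifth-order low-pass at `low_cut` followed by a fifth-order high-pass
#' at `high_cut` (an LTI band-pass either way round). Zero-phase
#' (forward-backward) by default, which squares the magnitude response;
#' `causal = TRUE` applies each filter once.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param low_cut,high_cut cutoffs in Hz.
#' @param order filter order per stage.
#' @param causal single-pass filtering when `TRUE`.
#' @export
emg_bandpass <- function(x, fs, low_cut = 30, high_cut = 4, order = 5,
                         causal = FALSE) {
  stopifnot(fs > 2 * low_cut, high_cut < low_cut)
  lp <- signal::butter(order, low_cut / (fs / 2), type = "low")
  hp <- signal::butter(order, high_cut / (fs / 2), type = "high")
  if (causal) {
    as.numeric(signal::filter(hp, as.numeric(signal::filter(lp, x))))
  } else {
    as.numeric(signal::filtfilt(hp, as.numeric(signal::filtfilt(lp, x))))
  }
}

#' EMG preprocessing chain
#'
#' Per channel, in this order: fifth-order Butterworth low-pass at 30 Hz,
#' fifth-order Butterworth high-pass at 4 Hz, mean subtraction
#' (detrend), full-wave rectification (absolute value), division by the
#' channel maximum, division by the channel SD. Every output channel has
#' unit variance and is non-negative. Filtering is zero-phase
#' (forward-backward) by default; `causal = TRUE` gives the single-pass
#' filter instead.
#'
#' @param segment an `emg_segment` (muscles x samples).
#' @param low_cut,high_cut filter cutoffs in Hz (defaults 30 and 4).
#' @param order Butterworth order (default 5).
#' @param causal logical; single-pass filtering when `TRUE`.
#' @return the preprocessed `emg_segment`.
#' @export
preprocess_emg <- function(segment, low_cut = 30, high_cut = 4, order = 5,
                           causal = FALSE) {
  stopifnot(inherits(segment, "emg_segment"))
  fs <- segment$fs
  if (fs <= 2 * low_cut) stop("preprocess_emg: fs must exceed twice the low-pass cutoff")
  n <- ncol(segment$matrix)
  if (n <= 3 * order) stop("preprocess_emg: segment too short for the filter order")
  out <- segment$matrix
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    if (all(x == 0)) {
      stop("preprocess_emg: all-zero channel ", rownames(out)[ch])
    }
    x <- emg_bandpass(x, fs, low_cut, high_cut, order, causal)
    x <- abs(x - mean(x))
    mx <- max(x)
    if (mx == 0) stop("preprocess_emg: degenerate (constant) channel ", rownames(out)[ch])
    x <- x / mx
    s <- stats::sd(x)
    if (s == 0) stop("preprocess_emg: zero-variance channel ", rownames(out)[ch])
    out[ch, ] <- x / s
  }
  new_emg_segment(out, fs, segment$provenance)
}
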