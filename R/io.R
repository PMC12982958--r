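fmt17 <- function(x) sprintf("%.17g", x)

#' Sensor CSV round-trip
#'
#' Schema: `time_s,sensor_id,qw,qx,qy,qz`, one row per sample, floats at
#' 17 significant digits so write/read round-trips are lossless.
#'
#' @param stream a [sensor_stream()].
#' @param path file path.
#' @export
write_sensor_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- data.frame(time_s = fmt17(stream$time_s), sensor_id = stream$sensor_id,
                   qw = fmt17(stream$q[, 1]), qx = fmt17(stream$q[, 2]),
                   qy = fmt17(stream$q[, 3]), qz = fmt17(stream$q[, 4]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @param nominal_rate nominal rate attached on read (default 74 Hz).
#' @export
read_sensor_csv <- function(path, nominal_rate = 74) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "sensor_id", "qw", "qx", "qy", "qz")
  if (!identical(names(df), need)) {
    stop("read_sensor_csv: expected header ", paste(need, collapse = ","),
         " in ", path)
  }
  num <- c("time_s", "qw", "qx", "qy", "qz")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad)) {
      stop(sprintf("read_sensor_csv: malformed %s at line %d of %s",
                   cl, bad[1] + 1L, path))
    }
    df[[cl]] <- v
  }
  ids <- unique(df$sensor_id)
  if (length(ids) != 1L) stop("read_sensor_csv: multiple sensor ids in ", path)
  if (!ids %in% c("thigh_BF", "midshank", "trunk")) {
    stop("read_sensor_csv: unknown sensor_id '", ids, "'")
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("read_sensor_csv: timestamps out of order in ", path)
  }
  sensor_stream(df$time_s, as.matrix(df[, c("qw", "qx", "qy", "qz")]),
                ids, nominal_rate = nominal_rate)
}

#' EMG CSV round-trip
#'
#' Schema: `time_s,TA,GAM,GLM,GL,PL,BF,RF` (fixed muscle order).
#'
#' @param stream an [emg_stream()].
#' @param path file path.
#' @export
write_emg_csv <- function(stream, path) {
  stopifnot(inherits(stream, "emg_stream"))
  df <- cbind(data.frame(time_s = fmt17(stream$time_s)),
              as.data.frame(apply(stream$values, 2, fmt17)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param fs sampling rate; inferred from the median timestamp spacing
#'   when `NULL`.
#' @export
read_emg_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", emg_muscles)
  if (!identical(names(df), need)) {
    stop("read_emg_csv: expected header ", paste(need, collapse = ","),
         " in ", path)
  }
  for (cl in need) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad)) {
      stop(sprintf("read_emg_csv: malformed %s at line %d of %s",
                   cl, bad[1] + 1L, path))
    }
    df[[cl]] <- v
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("read_emg_csv: timestamps out of order in ", path)
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time_s))
  emg_stream(df$time_s, as.matrix(df[, emg_muscles]), fs)
}

#' Event-log JSONL round-trip
#'
#' One JSON object per line:
#' `{"t": float, "kind": str, "trail": int|null, "group": int|null,
#' "ordinal": int|null, "prompt": str|null}`.
#'
#' @param events event-log data frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    rec <- list(t = events$t[i], kind = events$kind[i],
                trail = events$trail[i], group = events$group[i],
                ordinal = events$ordinal[i], prompt = events$prompt[i])
    rec <- lapply(rec, function(v) if (length(v) == 1 && is.na(v)) NULL else v)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("read_events: malformed JSON at line ",
                                             i, " of ", path))
    data.frame(
      t = as.numeric(rec$t), kind = as.character(rec$kind),
      trail = if (is.null(rec$trail)) NA_integer_ else as.integer(rec$trail),
      group = if (is.null(rec$group)) NA_integer_ else as.integer(rec$group),
      ordinal = if (is.null(rec$ordinal)) NA_integer_ else as.integer(rec$ordinal),
      prompt = if (is.null(rec$prompt)) NA_character_ else as.character(rec$prompt),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Calibration result JSON round-trip
#'
#' Keys: `q0`, `q_ref` and `q_T` per sensor id, `buffer_len`.
#'
#' @param calib a [calibrate_sensors()] result.
#' @param path file path.
#' @export
write_calibration_json <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_result"))
  obj <- list(q0 = unclass(calib$q0),
              q_ref = lapply(calib$q_ref, unclass),
              q_T = lapply(calib$q_T, unclass),
              buffer_len = calib$buffer_len)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE), path)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(
    q0 = quat(as.numeric(obj$q0)),
    q_ref = lapply(obj$q_ref, function(v) quat(as.numeric(v))),
    q_T = lapply(obj$q_T, function(v) quat(as.numeric(v))),
    buffer_len = as.integer(obj$buffer_len)
  ), class = "calibration_result")
}
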