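#' Orientation sensor streams
#'
#' A `sensor_stream` is a time-indexed sequence of unit orientation
#' quaternions from one inertial sensor. Valid sensor labels follow the
#' study montage: `thigh_BF` (biceps femoris site), `midshank`, `trunk`.
#'
#' @param time_s numeric vector of strictly increasing sample times (s).
#' @param quaternions n x 4 matrix `(w, x, y, z)`, unit rows within `1e-6`.
#' @param sensor_id one of `"thigh_BF"`, `"midshank"`, `"trunk"`.
#' @param nominal_rate nominal sampling rate in Hz (study hardware: 74).
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(time_s, quaternions, sensor_id,
                          nominal_rate = 74) {
  sensor_id <- match.arg(sensor_id, c("thigh_BF", "midshank", "trunk"))
  quaternions <- as.matrix(quaternions)
  stopifnot(ncol(quaternions) == 4L, length(time_s) == nrow(quaternions))
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("sensor_stream: time must be strictly increasing")
  }
  norms <- sqrt(rowSums(quaternions^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("sensor_stream: quaternions must be unit-norm within 1e-6 on ingest")
  }
  structure(
    list(time_s = as.numeric(time_s), q = unname(quaternions),
         sensor_id = sensor_id, nominal_rate = nominal_rate),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream %s: %d samples, %.3f-%.3f s, %g Hz nominal>\n",
              x$sensor_id, length(x$time_s),
              min(x$time_s), max(x$time_s), x$nominal_rate))
  invisible(x)
}

#' Average a buffer of unit quaternions
#'
#' Component-wise mean after hemisphere alignment (each sample is flipped
#' to have non-negative dot product with the first), then renormalized.
#' This is the reference-orientation estimate used by the flat-surface and
#' upright calibration stages.
#'
#' @param buffer n x 4 matrix of unit quaternions, or a list of [quat()]s.
#' @return a unit [quat()].
#' @export
average_quaternions <- function(buffer) {
  if (is.list(buffer)) buffer <- do.call(rbind, lapply(buffer, unclass))
  buffer <- as.matrix(buffer)
  if (nrow(buffer) == 0L) stop("average_quaternions: empty buffer")
  flip <- sign(buffer %*% buffer[1, ])
  flip[flip == 0] <- 1
  m <- colMeans(buffer * as.vector(flip))
  if (sqrt(sum(m^2)) < 1e-8) {
    stop("average_quaternions: mean has near-zero norm (degenerate buffer)")
  }
  q_normalize(quat(m))
}

#' Two-stage calibration offset
#'
#' `compute_offset` returns the per-sensor correction `q_T` such that the
#' upright-pose orientation `q_ref` maps back onto the flat-surface
#' baseline `q0`, removing mounting bias due to limb shape:
#' `q_T = conj(q_ref) * q0`, with `apply_calibration(qR, qT) = qR * qT`.
#'
#' @param q0 flat-surface baseline orientation (unit quaternion).
#' @param q_ref upright-pose mean orientation of the sensor.
#' @return `q_T` as a unit [quat()].
#' @export
compute_offset <- function(q0, q_ref) {
  for (q in list(q0, q_ref)) {
    if (abs(q_norm(q) - 1) > 1e-6) stop("compute_offset: inputs must be unit quaternions")
  }
  q_normalize(q_multiply(q_conjugate(quat(unclass(q_ref))), quat(unclass(q0))))
}

#' @rdname compute_offset
#' @param qR measured in-task orientation.
#' @param qT calibration offset from [compute_offset()].
#' @export
apply_calibration <- function(qR, qT) {
  q_normalize(q_multiply(quat(unclass(qR)), quat(unclass(qT))))
}

#' Relative knee rotation between calibrated segment frames
#'
#' Rotation taking the calibrated shank frame to the calibrated thigh
#' frame; identity when the two frames coincide (upright stance).
#'
#' @param q_thigh_cal,q_shank_cal calibrated unit quaternions.
#' @export
knee_relative_rotation <- function(q_thigh_cal, q_shank_cal) {
  q_normalize(q_multiply(q_conjugate(quat(unclass(q_shank_cal))),
                         quat(unclass(q_thigh_cal))))
}

# Euler Y (intrinsic Y-X-Z) of a batch of quaternions, degrees in (-180,180].
# Near the gimbal singularity (|pitch| -> 90 deg) falls back to the
# axis-angle magnitude projected on the Y axis (deterministic, continuous
# enough for the sagittal-plane motion this pipeline measures).
euler_y_deg <- function(Q) {
  Q <- qm_normalize(as.matrix(Q))
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  r13 <- 2 * (x * z + w * y)
  r33 <- 1 - 2 * (x^2 + y^2)
  r23 <- 2 * (y * z - w * x)   # = -sin(pitch)
  out <- atan2(r13, r33) * 180 / pi
  gimbal <- abs(r23) > 1 - 1e-9
  if (any(gimbal)) {
    vnorm <- sqrt(x^2 + y^2 + z^2)
    theta <- 2 * atan2(vnorm, abs(w)) * 180 / pi
    axis_y <- ifelse(vnorm > 0, y * sign(w) / pmax(vnorm, 1e-300), 0)
    out[gimbal] <- (theta * axis_y)[gimbal]
  }
  out
}

#' Knee angle from the relative knee rotation
#'
#' Reads the Y (sagittal-plane) Euler component of the knee rotation. For
#' a pure Y rotation of magnitude `theta` in `[0, 180]` degrees the
#' flexion angle is `theta` and the included (anatomical) angle is
#' `180 - theta`; upright stance gives flexion 0, included 180.
#'
#' @param q_knee relative rotation from [knee_relative_rotation()].
#' @param convention `"included"` (default; 180 = fully straight) or
#'   `"flexion"`.
#' @return angle in degrees, always within `[0, 180]`.
#' @export
knee_angle_y <- function(q_knee, convention = c("included", "flexion")) {
  convention <- match.arg(convention)
  flex <- pmin(abs(euler_y_deg(matrix(unclass(q_knee), ncol = 4))), 180)
  if (convention == "flexion") flex else 180 - flex
}

#' Convert between included and flexion knee-angle conventions
#'
#' The conversion `x -> 180 - x` is an exact involution.
#' @param angle_deg numeric vector of angles in degrees within `[0, 180]`.
#' @export
included_to_flexion <- function(angle_deg) 180 - angle_deg

#' @rdname included_to_flexion
#' @export
flexion_to_included <- function(angle_deg) 180 - angle_deg

#' Knee-angle time series
#'
#' @param time_s sample times (s), strictly increasing.
#' @param included_deg included knee angle per sample, degrees in `[0, 180]`.
#' @return object of class `knee_angle_series` (data frame with columns
#'   `time_s`, `included_deg`).
#' @export
knee_angle_series <- function(time_s, included_deg) {
  stopifnot(length(time_s) == length(included_deg))
  if (any(included_deg < -1e-9 | included_deg > 180 + 1e-9)) {
    stop("knee_angle_series: included angle outside [0, 180] degrees")
  }
  structure(
    data.frame(time_s = as.numeric(time_s),
               included_deg = pmin(pmax(included_deg, 0), 180)),
    class = c("knee_angle_series", "data.frame")
  )
}

#' Calibrate a thigh/shank sensor pair
#'
#' Stage one: both sensors lie parallel on a flat surface; the last
#' `buffer_len` samples of each 14 s recording are averaged and pooled
#' into the shared baseline `q0`. Stage two: the participant stands
#' upright; the per-sensor mean is `q_ref`, and `q_T = conj(q_ref) * q0`
#' is the per-sensor correction applied to every in-task sample.
#'
#' @param flat named list of `sensor_stream`s (or n x 4 matrices) recorded
#'   on the flat surface, names = sensor ids.
#' @param upright named list of the upright-stance recordings, same names.
#' @param buffer_len number of trailing samples used per buffer
#'   (default 1000, matching a 14 s recording at 74 Hz).
#' @return object of class `calibration_result`: `q0`, per-sensor `q_ref`
#'   and `q_T`, and `buffer_len`.
#' @export
calibrate_sensors <- function(flat, upright, buffer_len = 1000) {
  stopifnot(length(flat) >= 1, identical(sort(names(flat)), sort(names(upright))))
  take <- function(s) {
    Q <- if (inherits(s, "sensor_stream")) s$q else as.matrix(s)
    n <- nrow(Q)
    Q[seq.int(max(1L, n - buffer_len + 1L), n), , drop = FALSE]
  }
  flat_means <- lapply(flat, function(s) average_quaternions(take(s)))
  q0 <- average_quaternions(do.call(rbind, lapply(flat_means, unclass)))
  q_ref <- lapply(upright, function(s) average_quaternions(take(s)))
  q_T <- lapply(q_ref, function(qr) compute_offset(q0, qr))
  structure(list(q0 = q0, q_ref = q_ref, q_T = q_T, buffer_len = buffer_len),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result: %d sensors, buffer_len=%d>\n",
              length(x$q_T), x$buffer_len))
  invisible(x)
}

#' Knee-angle series from calibrated thigh and shank streams
#'
#' Pairs thigh and shank samples by nearest neighbour within half the
#' nominal sample period (no interpolation), applies the per-sensor
#' calibration, and extracts the included knee angle per paired sample.
#'
#' @param thigh,shank `sensor_stream`s for `thigh_BF` and `midshank`.
#' @param calib a [calibrate_sensors()] result containing both sensor ids.
#' @return a [knee_angle_series()].
#' @export
stream_knee_angle <- function(thigh, shank, calib) {
  stopifnot(inherits(thigh, "sensor_stream"), inherits(shank, "sensor_stream"),
            inherits(calib, "calibration_result"))
  for (id in c(thigh$sensor_id, shank$sensor_id)) {
    if (!id %in% names(calib$q_T)) stop("stream_knee_angle: no calibration for sensor ", id)
  }
  half_period <- 0.5 / thigh$nominal_rate
  if (min(shank$time_s) > max(thigh$time_s) + half_period ||
      min(thigh$time_s) > max(shank$time_s) + half_period) {
    stop("stream_knee_angle: streams have no temporal overlap")
  }
  idx <- findInterval(thigh$time_s, shank$time_s)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(shank$time_s))
  d_lo <- abs(thigh$time_s - shank$time_s[lo])
  d_hi <- abs(shank$time_s[hi] - thigh$time_s)
  nn <- ifelse(d_hi < d_lo, hi, lo)
  keep <- pmin(d_lo, d_hi) <= half_period
  if (!any(keep)) stop("stream_knee_angle: no sample pairs within half a period")
  Qt <- qm_multiply(thigh$q[keep, , drop = FALSE], calib$q_T[[thigh$sensor_id]])
  Qs <- qm_multiply(shank$q[nn[keep], , drop = FALSE], calib$q_T[[shank$sensor_id]])
  Qrel <- qm_multiply(qm_conjugate(Qs), Qt)
  flex <- pmin(abs(euler_y_deg(Qrel)), 180)
  knee_angle_series(thigh$time_s[keep], 180 - flex)
}
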