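#' Unit quaternion constructors and algebra
#'
#' Quaternions are represented as numeric vectors `c(w, x, y, z)` (scalar
#' first, Hamilton convention). Batches of quaternions are n x 4 matrices
#' with the same column order. All rotation-level operations are invariant
#' to a global sign flip, since `q` and `-q` encode the same rotation.
#'
#' @param w,x,y,z real components, or `w` a length-4 numeric vector.
#' @return a numeric vector of class `quat`.
#' @examples
#' quat(1, 0, 0, 0)                  # identity rotation
#' q_from_axis_angle(c(0, 1, 0), 90) # quarter turn about Y
#' @export
quat <- function(w, x = NULL, y = NULL, z = NULL) {
  if (is.null(x)) {
    stopifnot(is.numeric(w), length(w) == 4L)
    q <- as.numeric(w)
  } else {
    q <- c(w, x, y, z)
  }
  if (any(!is.finite(q))) stop("quaternion components must be finite")
  structure(q, class = "quat", names = c("w", "x", "y", "z"))
}

#' @export
print.quat <- function(x, ...) {
  cat(sprintf("<quat w=%.6g x=%.6g y=%.6g z=%.6g>\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

q_norm <- function(q) sqrt(sum(unclass(q)^2))

#' Normalize a quaternion to unit length
#'
#' @param q a [quat()] or length-4 numeric vector.
#' @return unit quaternion representing the same rotation.
#' @export
q_normalize <- function(q) {
  n <- q_norm(q)
  if (n < .Machine$double.eps^0.5) {
    stop("cannot normalize a (near-)zero quaternion")
  }
  quat(unclass(q) / n)
}

#' @rdname q_normalize
#' @export
q_conjugate <- function(q) quat(q[1], -q[2], -q[3], -q[4])

#' Hamilton product of two quaternions
#'
#' @param a,b quaternions (`c(w, x, y, z)`).
#' @return the product `a %q% b` as a [quat()].
#' @export
q_multiply <- function(a, b) {
  quat(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Axis-angle construction and extraction
#'
#' @param axis length-3 direction (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return `q_from_axis_angle`: a unit [quat()]; `q_rotation_angle`: the
#'   rotation magnitude in degrees within `[0, 180]`.
#' @export
q_from_axis_angle <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  quat(cos(half), a[1] * sin(half), a[2] * sin(half), a[3] * sin(half))
}

#' @rdname q_from_axis_angle
#' @param q a quaternion.
#' @export
q_rotation_angle <- function(q) {
  q <- q_normalize(q)
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

#' Angular distance between two rotations, in degrees
#'
#' Sign-invariant: `q` and `-q` are the same rotation.
#' @param a,b unit quaternions.
#' @export
q_angle_between <- function(a, b) {
  q_rotation_angle(q_multiply(q_conjugate(quat(unclass(a))), quat(unclass(b))))
}

#' Rotation matrix of a unit quaternion
#'
#' @param q unit quaternion.
#' @return 3x3 orthogonal matrix. Invariant to the sign of `q`.
#' @export
q_to_matrix <- function(q) {
  q <- q_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# ---- vectorized (matrix, n x 4) kernels used by the stream pipeline ----

qm_normalize <- function(Q) {
  n <- sqrt(rowSums(Q^2))
  if (any(n < .Machine$double.eps^0.5)) stop("zero-norm quaternion in batch")
  Q / n
}

# rowwise Hamilton product of two n x 4 matrices (or one matrix and one quat)
qm_multiply <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(unclass(A), nrow = nrow(B), ncol = 4, byrow = TRUE)
  if (is.null(dim(B))) B <- matrix(unclass(B), nrow = nrow(A), ncol = 4, byrow = TRUE)
  cbind(
    A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
    A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
    A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
    A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1]
  )
}

qm_conjugate <- function(Q) cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
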