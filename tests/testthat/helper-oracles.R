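# Independent oracles used across the suite.

# Brute-force Mann-Whitney null distribution: enumerate every way to
# choose which ranks belong to the first sample and count U values.
brute_force_u_counts <- function(n1, n2) {
  n <- n1 + n2
  sets <- utils::combn(n, n1)
  u <- colSums(sets) - n1 * (n1 + 1) / 2
  counts <- numeric(n1 * n2 + 1)
  for (v in u) counts[v + 1] <- counts[v + 1] + 1
  counts
}

# Compose two rotations via their 3x3 matrices and recover the angle.
matrix_compose_angle <- function(qa, qb) {
  R <- q_to_matrix(qa) %*% q_to_matrix(qb)
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

# Sort-based quantile oracle (linear interpolation between order
# statistics at positions 1 + p * (n - 1); the inclusive method).
sort_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + p * (n - 1)
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Random unit quaternion.
random_quat <- function() {
  v <- stats::rnorm(4)
  q_normalize(quat(v))
}

# Best rank-1 non-negative approximation of a small matrix by grid
# search over the direction of w (h solved in closed form given w).
grid_rank1_vaf <- function(E, n_grid = 2000) {
  best <- 0
  for (a in seq(0, pi / 2, length.out = n_grid)) {
    w <- c(cos(a), sin(a))
    h <- pmax(crossprod(E, w), 0)          # optimal non-negative h | w
    vaf_a <- 1 - sum((E - w %*% t(h))^2) / sum(E^2)
    if (vaf_a > best) best <- vaf_a
  }
  best
}
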