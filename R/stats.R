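#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, over all `choose(n1 + n2, n1)` equally likely rank
#' assignments, how many yield each value of U. Computed with the
#' standard recurrence `N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1)`
#' (equivalently, partitions of `u` into at most `m` parts each at most
#' `n`). The distribution is symmetric about `n1 * n2 / 2`.
#'
#' @param n1,n2 sample sizes; exact mode requires `n1 + n2 <= 25`.
#' @return a list: `u` (0 to `n1*n2`), `count`, `prob`, `total`.
#' @export
exact_u_distribution <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (n1 + n2 > 25) {
    stop("exact_u_distribution: exact mode limited to n1 + n2 <= 25; ",
         "use the normal approximation")
  }
  umax <- n1 * n2
  # C(m, n)[u]: conditioning on whether the largest pooled value is from
  # the first sample (beats all n of the second: shift by n) or not:
  # C(m, n)[u] = C(m-1, n)[u - n] + C(m, n-1)[u]; C(0, .) = C(., 0) = d_0.
  prev <- matrix(0, nrow = n1 + 1, ncol = umax + 1)   # column n' = 0
  prev[, 1] <- 1
  cur <- prev
  for (np in seq_len(n2)) {
    cur <- matrix(0, nrow = n1 + 1, ncol = umax + 1)
    cur[1, 1] <- 1
    for (m in seq_len(n1)) {
      u <- 0:(m * np)
      shifted <- ifelse(u - np >= 0, cur[m, pmax(u - np, 0) + 1], 0)
      cur[m + 1, u + 1] <- shifted + prev[m + 1, u + 1]
    }
    prev <- cur
  }
  count <- cur[n1 + 1, ]
  total <- choose(n1 + n2, n1)
  stopifnot(isTRUE(all.equal(sum(count), total)))
  list(u = 0:umax, count = count, prob = count / total, total = total)
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' U is computed from rank sums with midranks for ties. Without ties and
#' with `n1 + n2 <= 25` the p-value comes from the exact enumeration of
#' [exact_u_distribution()]; otherwise a normal approximation with tie
#' correction and continuity correction is used. The one-sided
#' alternative `"greater"` asks whether `x` is stochastically greater
#' than `y` (`p = P(U >= U_obs)`); the two-sided p-value is twice the
#' smaller tail, capped at 1.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"`, `"less"`, or `"two_sided"`.
#' @return object of class `rank_test_result`: `U`, `p`, plus
#'   `p_one_sided_greater`, `p_one_sided_less`, `p_two_sided`, `method`,
#'   `n1`, `n2`.
#' @examples
#' mann_whitney(c(11:17), c(1:7), "greater")  # complete separation
#' @export
mann_whitney <- function(x, y,
                         alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("mann_whitney: empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n1 + n2 <= 25) {
    d <- exact_u_distribution(n1, n2)
    p_ge <- sum(d$prob[d$u >= U])
    p_le <- sum(d$prob[d$u <= U])
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1))))
    p_ge <- stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((U - mu + 0.5) / sigma)
    method <- "normal_approx"
  }
  p_two <- min(1, 2 * min(p_ge, p_le))
  p <- switch(alternative, greater = p_ge, less = p_le, two_sided = p_two)
  structure(
    list(U = U, p = p, alternative = alternative, method = method,
         p_one_sided_greater = p_ge, p_one_sided_less = p_le,
         p_two_sided = p_two, n1 = n1, n2 = n2),
    class = "rank_test_result"
  )
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s)\n", x$method, x$alternative))
  cat(sprintf("  U = %.1f (n1 = %d, n2 = %d), p = %.4g\n", x$U, x$n1, x$n2, x$p))
  cat(sprintf("  one-sided greater p = %.4g, two-sided p = %.4g\n",
              x$p_one_sided_greater, x$p_two_sided))
  invisible(x)
}

#' Median and quartiles
#'
#' Inclusive linear-interpolation quantiles (type 7).
#' @param values non-empty numeric vector.
#' @return list with `median`, `q1`, `q3`.
#' @export
describe <- function(values) {
  stopifnot(length(values) >= 1)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Programmatic normal Q-Q screening
#'
#' Correlation between sample order statistics and normal quantiles
#' (a numeric stand-in for visual Q-Q inspection).
#'
#' @param values numeric vector, length >= 4.
#' @param threshold minimum correlation to call the sample plausibly
#'   normal (default 0.95).
#' @return list with `r` and logical `plausibly_normal`.
#' @export
qq_normality_check <- function(values, threshold = 0.95) {
  stopifnot(length(values) >= 4)
  n <- length(values)
  theo <- stats::qnorm(stats::ppoints(n))
  r <- stats::cor(sort(values), theo)
  list(r = r, plausibly_normal = is.finite(r) && r >= threshold)
}

#' Power of a between-groups repeated-measures ANOVA
#'
#' Noncentral-F power for the between-subjects factor: with effect size
#' `f`, total N over `n_groups` balanced groups, `m` repeated
#' measurements correlated `rho`, the noncentrality is
#' `lambda = f^2 * N * m / (1 + (m - 1) * rho)` on
#' `df1 = n_groups - 1`, `df2 = N - n_groups`.
#'
#' @param N total sample size (balanced groups).
#' @param effect_f Cohen's f for the between factor.
#' @param alpha significance level.
#' @param n_groups number of groups (default 2).
#' @param m number of repeated measurements (default 2).
#' @param rho assumed correlation among repeated measures (default 0.5).
#' @return achieved power in `(0, 1)`.
#' @export
rm_anova_power <- function(N, effect_f, alpha = 0.05, n_groups = 2,
                           m = 2, rho = 0.5) {
  stopifnot(N > n_groups, effect_f >= 0, rho > -1, rho < 1)
  lambda <- effect_f^2 * N * m / (1 + (m - 1) * rho)
  df1 <- n_groups - 1
  df2 <- N - n_groups
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' A-priori sample size for the between factor
#'
#' Smallest total N (multiple of `n_groups`, balanced) whose
#' [rm_anova_power()] reaches `target_power`.
#'
#' @inheritParams rm_anova_power
#' @param target_power desired power (default 0.80).
#' @param max_N search cap (default 10000).
#' @return total N as an integer.
#' @export
required_sample_size <- function(effect_f = 0.78, alpha = 0.05,
                                 target_power = 0.80, n_groups = 2,
                                 m = 2, rho = 0.5, max_N = 10000) {
  stopifnot(effect_f > 0, target_power > 0, target_power < 1)
  N <- 2 * n_groups
  while (N <= max_N) {
    if (rm_anova_power(N, effect_f, alpha, n_groups, m, rho) >= target_power) {
      return(as.integer(N))
    }
    N <- N + n_groups
  }
  stop("required_sample_size: target power unreachable within N <= ", max_N)
}

#' Score Intrinsic Motivation Inventory subscales
#'
#' Items are rated 1-7 (1 = not at all true, 4 = somewhat true, 7 = very
#' true). Reverse-scored items are mapped `x -> 8 - x` before
#' aggregation. Aggregation modes: `"sum"` (raw item sum, default),
#' `"mean"`, or `"centered_sum"` (sum of `item - 4`, which can go
#' negative for low-rated subscales such as pressure/tension).
#'
#' @param subscales named list of numeric item vectors (values in 1..7).
#' @param reverse named list of reverse-scored item indices per subscale.
#' @param mode aggregation mode.
#' @return named numeric vector of subscale scores.
#' @export
score_imi <- function(subscales, reverse = list(),
                      mode = c("sum", "mean", "centered_sum")) {
  mode <- match.arg(mode)
  vapply(names(subscales), function(nm) {
    items <- as.numeric(subscales[[nm]])
    if (any(items < 1 | items > 7)) {
      stop("score_imi: items of '", nm, "' outside [1, 7]")
    }
    ri <- reverse[[nm]]
    if (!is.null(ri)) items[ri] <- 8 - items[ri]
    switch(mode, sum = sum(items), mean = mean(items),
           centered_sum = sum(items - 4))
  }, numeric(1))
}

ueq_pragmatic_dims <- c("perspicuity", "efficiency", "dependability")
ueq_hedonic_dims <- c("stimulation", "novelty")

#' Pragmatic and hedonic quality from UEQ dimension means
#'
#' Pragmatic quality is the mean of the perspicuity, efficiency and
#' dependability dimensions; hedonic quality the mean of stimulation and
#' novelty.
#'
#' @param dim_means named numeric vector of UEQ dimension means (at least
#'   the five dimensions above; values in `[-3, 3]`).
#' @return list with `pragmatic` and `hedonic`.
#' @export
ueq_quality <- function(dim_means) {
  need <- c(ueq_pragmatic_dims, ueq_hedonic_dims)
  if (!all(need %in% names(dim_means))) {
    stop("ueq_quality: missing dimensions: ",
         paste(setdiff(need, names(dim_means)), collapse = ", "))
  }
  list(pragmatic = mean(dim_means[ueq_pragmatic_dims]),
       hedonic = mean(dim_means[ueq_hedonic_dims]))
}

#' Score User Experience Questionnaire dimensions
#'
#' Items are bipolar adjective pairs rated -3..+3. Dimension scores are
#' item means after sign correction of reversed items; pragmatic and
#' hedonic quality are aggregated with [ueq_quality()].
#'
#' @param dimensions named list of numeric item vectors (values in
#'   `[-3, 3]`); names must include attractiveness, perspicuity,
#'   efficiency, dependability, stimulation, novelty.
#' @param reverse named list of reversed item indices per dimension
#'   (reversed items are negated).
#' @return list with `dimensions` (named means), `pragmatic`, `hedonic`.
#' @export
score_ueq <- function(dimensions, reverse = list()) {
  means <- vapply(names(dimensions), function(nm) {
    items <- as.numeric(dimensions[[nm]])
    if (any(items < -3 | items > 3)) {
      stop("score_ueq: items of '", nm, "' outside [-3, 3]")
    }
    ri <- reverse[[nm]]
    if (!is.null(ri)) items[ri] <- -items[ri]
    mean(items)
  }, numeric(1))
  qual <- ueq_quality(means)
  list(dimensions = means, pragmatic = qual$pragmatic, hedonic = qual$hedonic)
}
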