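test_that("the exact U distribution equals brute-force enumeration up to n = 8 + 8", {
  for (n1 in 1:8) {
    for (n2 in 1:8) {
      d <- exact_u_distribution(n1, n2)
      expect_equal(d$count, brute_force_u_counts(n1, n2))
      expect_equal(sum(d$count), choose(n1 + n2, n1))
      expect_equal(d$count, rev(d$count))   # symmetry about n1*n2/2
    }
  }
  d11 <- exact_u_distribution(1, 1)
  expect_equal(d11$count, c(1, 1))
  d77 <- exact_u_distribution(7, 7)
  expect_equal(d77$total, 3432)
  expect_equal(sum(d77$count[d77$u <= 8]), 65)
  expect_error(exact_u_distribution(13, 13), "exact mode")
})

test_that("the rank test reproduces hand-enumerable cases", {
  # complete separation at n = 7, 7: a single extreme assignment
  r <- mann_whitney(11:17, 1:7, "greater")
  expect_equal(r$U, 49)
  expect_equal(r$p, 1 / 3432)
  expect_equal(r$method, "exact")
  # identical multisets: U at its null mean (midranks)
  r2 <- mann_whitney(c(3, 1, 4), c(3, 1, 4), "two_sided")
  expect_equal(r2$U, 4.5)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("exact p-values agree with the base-R Wilcoxon oracle", {
  withr::with_seed(44, {
    for (i in 1:25) {
      x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
      r <- mann_whitney(x, y, "greater")
      w <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
      expect_equal(r$p, w$p.value, tolerance = 1e-12)
      r2 <- mann_whitney(x, y, "two_sided")
      w2 <- wilcox.test(x, y, alternative = "two.sided", exact = TRUE)
      expect_equal(r2$p, w2$p.value, tolerance = 1e-12)
    }
  })
})

test_that("p-values are invariant under strictly monotone transforms", {
  withr::with_seed(45, {
    x <- rnorm(7); y <- rnorm(7)
    p0 <- mann_whitney(x, y, "greater")$p
    expect_equal(mann_whitney(exp(x), exp(y), "greater")$p, p0)
    expect_equal(mann_whitney(x^3, y^3, "greater")$p, p0)
  })
})

test_that("descriptives match a sort-based quantile oracle", {
  expect_equal(describe(1:7)$median, 4)
  expect_equal(describe(c(1, 2, 3, 4))$median, 2.5)
  withr::with_seed(46, {
    for (i in 1:100) {
      v <- rnorm(sample(4:40, 1))
      d <- describe(v)
      expect_equal(d$median, sort_quantile(v, 0.5))
      expect_equal(d$q1, sort_quantile(v, 0.25))
      expect_equal(d$q3, sort_quantile(v, 0.75))
    }
  })
})

test_that("power search is monotone in effect size with the minimal-N limit", {
  n1 <- required_sample_size(effect_f = 0.78)
  n2 <- required_sample_size(effect_f = 1.56)
  expect_lte(n2, n1)
  expect_equal(required_sample_size(effect_f = 2, target_power = 1e-6), 4)
  # achieved power at the returned N crosses the target; N - 2 does not
  expect_gte(rm_anova_power(n1, 0.78), 0.80)
  expect_lt(rm_anova_power(n1 - 2, 0.78), 0.80)
  # oracle: power by numerical integration of the noncentral-F density
  lambda <- 0.78^2 * n1 * 2 / (1 + 0.5)
  fcrit <- qf(0.95, 1, n1 - 2)
  p_int <- integrate(function(x) df(x, 1, n1 - 2, ncp = lambda),
                     fcrit, Inf, rel.tol = 1e-10)$value
  expect_equal(rm_anova_power(n1, 0.78), p_int, tolerance = 1e-6)
})

test_that("motivation-inventory scoring handles reversal and the three modes", {
  items <- list(interest_enjoyment = rep(4, 7))
  expect_equal(unname(score_imi(items, mode = "mean")), 4)
  expect_equal(unname(score_imi(list(s = c(5, 2, 5)),
                                reverse = list(s = 2), mode = "sum")), 16)
  expect_equal(unname(score_imi(list(interest_enjoyment = rep(5, 7)))), 35)
  expect_equal(unname(score_imi(list(pressure_tension = c(2, 3, 2, 3, 4)),
                                mode = "centered_sum")), -6)
  expect_error(score_imi(list(s = c(0, 5))), "outside")
})

test_that("user-experience scoring aggregates pragmatic and hedonic quality", {
  dims <- list(attractiveness = c(3, 3), perspicuity = c(3, 3),
               efficiency = c(3, 3), dependability = c(3, 3),
               stimulation = c(3, 3), novelty = c(3, 3))
  s <- score_ueq(dims)
  expect_equal(unname(s$dimensions), rep(3, 6))
  expect_equal(s$pragmatic, 3)
  expect_equal(s$hedonic, 3)
  s2 <- score_ueq(list(attractiveness = 1, perspicuity = c(2, -2),
                       efficiency = 1, dependability = 2,
                       stimulation = -1, novelty = 0),
                  reverse = list(perspicuity = 2))
  expect_equal(unname(s2$dimensions["perspicuity"]), 2)
  expect_error(score_ueq(list(attractiveness = 4)), "outside")
})

test_that("the normality screen separates gaussian from heavy-tailed samples", {
  withr::with_seed(47, {
    expect_true(qq_normality_check(rnorm(200))$plausibly_normal)
    expect_false(qq_normality_check(rcauchy(200))$plausibly_normal)
  })
})
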