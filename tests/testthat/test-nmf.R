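rank3_data <- function(n = 400, seed = 3) {
  withr::with_seed(seed, {
    truth <- synergy_ground_truth()
    H <- matrix(0, 3, n)
    for (j in 1:3) {
      centers <- seq(20 + 100 * (j - 1), n, by = 300)
      for (c0 in centers) H[j, ] <- H[j, ] + exp(-((1:n) - c0)^2 / (2 * 15^2))
    }
    list(E = truth$W_true %*% H, W_true = truth$W_true, H = H)
  })
}

test_that("exact low-rank data is reconstructed perfectly at its rank", {
  d <- rank3_data()
  fit <- fit_nmf(d$E, 3, restarts = 5, seed = 1)
  expect_gte(fit$vaf, 0.999)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_equal(unname(sqrt(colSums(fit$W^2))), rep(1, 3), tolerance = 1e-9)
  expect_error(fit_nmf(d$E, 9), "k must be")
  expect_error(fit_nmf(-d$E, 2), "non-negative")
})

test_that("NMF fits are deterministic under a fixed seed", {
  d <- rank3_data()
  f1 <- fit_nmf(d$E, 2, restarts = 3, seed = 7)
  f2 <- fit_nmf(d$E, 2, restarts = 3, seed = 7)
  expect_identical(f1$W, f2$W)
  expect_false(identical(fit_nmf(d$E, 2, restarts = 3, seed = 8)$W, f1$W))
})

test_that("VAF follows its definition with clipping and degenerate guards", {
  d <- rank3_data()
  fit <- fit_nmf(d$E, 3, restarts = 3, seed = 2)
  expect_equal(vaf(d$E, fit), 1 - sum((d$E - fit$W %*% fit$H)^2) / sum(d$E^2))
  expect_equal(vaf(d$E, list(W = matrix(0, 7, 1), H = matrix(0, 1, ncol(d$E)))), 0)
  expect_error(vaf(matrix(0, 7, 5), fit), "zero-norm")
})

test_that("rank-1 VAF of the 2x2 identity matches a grid-search oracle", {
  E <- diag(2)
  oracle <- grid_rank1_vaf(E)     # exhaustive direction search
  fit <- fit_nmf(E, 1, restarts = 10, seed = 4)
  expect_equal(fit$vaf, oracle, tolerance = 1e-3)
})

test_that("VAF is non-decreasing in the synergy count with nested warm starts", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      E <- matrix(runif(7 * 60), 7, 60)
      sel <- select_synergy_number(E, threshold = 99.999, restarts = 2,
                                   seed = rep, max_iter = 300)
      expect_true(all(diff(sel$vaf_by_k) >= -1e-9))
      expect_gte(sel$vaf_by_k[7], max(sel$vaf_by_k[1:6]))
    }
  })
})

test_that("synergy-number selection hits the generative rank at all thresholds", {
  d <- rank3_data()
  for (th in c(80, 85, 90)) {
    expect_equal(select_synergy_number(d$E, threshold = th, restarts = 3,
                                       seed = 5)$k, 3)
  }
  # threshold near zero selects a single synergy
  expect_equal(select_synergy_number(d$E, threshold = 1e-6, restarts = 2,
                                     seed = 5)$k, 1)
})

test_that("synergy matching is permutation- and scale-invariant", {
  withr::with_seed(23, {
    W <- matrix(runif(7 * 4), 7, 4)
    perm <- sample(4)
    m <- match_synergies(W, W[, perm])
    expect_equal(m$pairs$cosine, rep(1, 4), tolerance = 1e-12)
    expect_equal(perm[m$pairs$col_b], m$pairs$col_a)
    # column rescaling leaves cosines at 1
    m2 <- match_synergies(W, sweep(W, 2, c(0.2, 3, 1, 10), "*"))
    expect_equal(m2$pairs$cosine, rep(1, 4), tolerance = 1e-12)
    # orthogonal columns, shuffled, plus 1% noise
    Wo <- diag(7)[, 1:4]
    Wn <- Wo[, sample(4)] + matrix(runif(28, 0, 0.01), 7, 4)
    expect_true(all(match_synergies(Wo, Wn)$pairs$cosine >= 0.99))
    # unequal counts: surplus reported unmatched
    m3 <- match_synergies(W[, 1:2], W)
    expect_equal(nrow(m3$pairs), 2)
    expect_length(m3$unmatched_b, 2)
  })
})

test_that("generative weights are recovered from noisy mixtures", {
  em <- {
    sch <- fish_schedule(n_fish = 4, rng_seed = 9)
    ev <- simulate_events(sch, seed = 9)
    gen_emg(ev, synergy_ground_truth(), fs = 250, snr_db = 20, seed = 9)
  }
  gt <- attr(em, "ground_truth")
  fit <- fit_nmf(t(em$values), 3, restarts = 5, seed = 10)
  m <- match_synergies(fit$W, gt$W_true)
  expect_gte(m$mean_cosine, 0.95)
})
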