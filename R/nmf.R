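# One multiplicative-update NMF run (Frobenius loss, Lee-Seung updates)
# from a given non-negative initialization. Returns W, H and the final
# relative reconstruction error.
nmf_run <- function(V, W, H, max_iter = 1000, tol = 1e-6) {
  eps <- .Machine$double.eps
  vnorm <- sqrt(sum(V^2))
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2)) / max(vnorm, eps)
      if (abs(err_prev - err) < tol) break
      err_prev <- err
    }
  }
  list(W = W, H = H, err = sqrt(sum((V - W %*% H)^2)) / max(vnorm, eps))
}

#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factorizes a non-negative muscles x samples matrix `E` as `W %*% H`
#' (synergy weights times activations) by multiplicative updates,
#' keeping the best of `restarts` seeded random initializations (lowest
#' reconstruction error). Columns of `W` are normalized to unit
#' Euclidean norm with the scale pushed into `H`.
#'
#' @param E non-negative matrix (or preprocessed `emg_segment`).
#' @param k number of synergies, `1 <= k <= nrow(E)`.
#' @param restarts random restarts (default 10).
#' @param seed integer seed; fixed seed gives a deterministic fit.
#' @param max_iter,tol update budget and relative-error convergence
#'   tolerance per run.
#' @param warm_start optional list(s) of `W`/`H` initializations tried in
#'   addition to the random restarts (used for nested model selection).
#' @return object of class `synergy_model`: `W` (muscles x k), `H`
#'   (k x samples), `vaf`, `k`.
#' @export
fit_nmf <- function(E, k, restarts = 10, seed = 1, max_iter = 1000,
                    tol = 1e-6, warm_start = NULL) {
  if (inherits(E, "emg_segment")) E <- E$matrix
  E <- as.matrix(E)
  if (any(E < 0)) stop("fit_nmf: input must be non-negative")
  m <- nrow(E)
  if (k < 1 || k > m) stop("fit_nmf: k must be in [1, ", m, "]")
  scale0 <- sqrt(mean(E) / k + .Machine$double.eps)
  best <- NULL
  with_seed(seed, {
    inits <- lapply(seq_len(restarts), function(i) {
      list(W = matrix(stats::runif(m * k, 0.1, 1) * scale0, m, k),
           H = matrix(stats::runif(k * ncol(E), 0.1, 1) * scale0, k, ncol(E)))
    })
    if (!is.null(warm_start)) {
      if (!is.null(warm_start$W)) warm_start <- list(warm_start)
      inits <- c(inits, warm_start)
    }
    for (ini in inits) {
      fit <- nmf_run(E, ini$W, ini$H, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$err < best$err) best <- fit
    }
  })
  cn <- sqrt(colSums(best$W^2))
  cn[cn == 0] <- 1
  W <- sweep(best$W, 2, cn, "/")
  H <- sweep(best$H, 1, cn, "*")
  structure(list(W = W, H = H, vaf = vaf(E, list(W = W, H = H)), k = k),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model: k = %d, VAF = %.4f>\n", x$k, x$vaf))
  invisible(x)
}

#' Variance accounted for by a synergy reconstruction
#'
#' `1 - ||E - W H||_F^2 / ||E||_F^2` with the uncentered total sum of
#' squares, clipped to `[0, 1]`.
#'
#' @param E non-negative data matrix (or `emg_segment`).
#' @param model a `synergy_model` or list with `W` and `H`.
#' @export
vaf <- function(E, model) {
  if (inherits(E, "emg_segment")) E <- E$matrix
  E <- as.matrix(E)
  tot <- sum(E^2)
  if (tot == 0) stop("vaf: zero-norm input matrix")
  resid <- sum((E - model$W %*% model$H)^2)
  min(max(1 - resid / tot, 0), 1)
}

#' Select the number of synergies by a VAF threshold
#'
#' Fits NMF for ascending `k` and returns the smallest `k` whose VAF
#' reaches `threshold` percent (`max_k` if none does). Each `k` reuses
#' the previous best fit, padded with one random component, as an extra
#' warm start, which makes the VAF sequence non-decreasing in `k`.
#'
#' @param E non-negative matrix or preprocessed `emg_segment`.
#' @param threshold VAF threshold in percent (study thresholds: 90, 85,
#'   80; default 85).
#' @param restarts,seed,max_iter,tol passed to [fit_nmf()].
#' @param max_k largest candidate (default `nrow(E)`).
#' @return list: `k` (selected count), `vaf_by_k`, `models` (per `k`
#'   fitted up to the selected one).
#' @export
select_synergy_number <- function(E, threshold = 85, restarts = 10, seed = 1,
                                  max_iter = 1000, tol = 1e-6, max_k = NULL) {
  if (inherits(E, "emg_segment")) E <- E$matrix
  E <- as.matrix(E)
  stopifnot(threshold > 0, threshold < 100)
  if (is.null(max_k)) max_k <- nrow(E)
  vafs <- numeric(0)
  models <- list()
  prev <- NULL
  selected <- max_k
  for (k in seq_len(max_k)) {
    ws <- NULL
    if (!is.null(prev)) {
      ws <- with_seed(seed + 1000L + k, {
        pad_w <- matrix(stats::runif(nrow(E)) * mean(prev$W), nrow(E), 1)
        pad_h <- matrix(stats::runif(ncol(E)) * mean(prev$H), 1, ncol(E))
        list(W = cbind(prev$W, pad_w), H = rbind(prev$H, pad_h))
      })
    }
    fit <- fit_nmf(E, k, restarts = restarts, seed = seed + k,
                   max_iter = max_iter, tol = tol, warm_start = ws)
    vafs[k] <- fit$vaf
    models[[k]] <- fit
    prev <- fit
    if (fit$vaf >= threshold / 100) {
      selected <- k
      break
    }
  }
  list(k = selected, vaf_by_k = vafs, models = models)
}

#' Match synergy weight vectors between two models
#'
#' Optimal one-to-one column assignment maximizing total cosine
#' similarity, by exhaustive permutation search (fine for up to 7
#' synergies). With unequal synergy counts the smaller set is matched
#' and the surplus columns reported unmatched.
#'
#' @param W_a,W_b muscles x k weight matrices (equal muscle count).
#' @return list: `pairs` (data frame `col_a`, `col_b`, `cosine`),
#'   `mean_cosine`, `unmatched_a`, `unmatched_b`.
#' @export
match_synergies <- function(W_a, W_b) {
  W_a <- as.matrix(W_a); W_b <- as.matrix(W_b)
  if (nrow(W_a) != nrow(W_b)) stop("match_synergies: muscle counts differ")
  norm_a <- sqrt(colSums(W_a^2)); norm_b <- sqrt(colSums(W_b^2))
  norm_a[norm_a == 0] <- 1; norm_b[norm_b == 0] <- 1
  C <- crossprod(sweep(W_a, 2, norm_a, "/"), sweep(W_b, 2, norm_b, "/"))
  ka <- ncol(W_a); kb <- ncol(W_b)
  swap <- ka > kb
  M <- if (swap) t(C) else C          # rows = smaller set
  k <- nrow(M)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best_p <- NULL; best_s <- -Inf
  for (p in perms(seq_len(ncol(M)))) {
    cand <- p[seq_len(k)]
    s <- sum(M[cbind(seq_len(k), cand)])
    if (s > best_s) { best_s <- s; best_p <- cand }
  }
  small_idx <- seq_len(k)
  if (swap) {
    pairs <- data.frame(col_a = best_p, col_b = small_idx,
                        cosine = M[cbind(small_idx, best_p)])
  } else {
    pairs <- data.frame(col_a = small_idx, col_b = best_p,
                        cosine = M[cbind(small_idx, best_p)])
  }
  pairs <- pairs[order(pairs$col_a), ]
  rownames(pairs) <- NULL
  list(pairs = pairs, mean_cosine = mean(pairs$cosine),
       unmatched_a = setdiff(seq_len(ka), pairs$col_a),
       unmatched_b = setdiff(seq_len(kb), pairs$col_b))
}
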