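# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code path with the package internals.

# per-row count of other rows within Chebyshev distance r
naive_match_counts <- function(V, r) {
  n <- nrow(V)
  cnt <- integer(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (max(abs(V[i, ] - V[j, ])) <= r) {
        cnt[i] <- cnt[i] + 1L
        cnt[j] <- cnt[j] + 1L
      }
    }
  }
  cnt
}

# composite delay vectors by explicit per-element loops
naive_cdvs <- function(X, M, tau, grow = 0L) {
  p <- nrow(X)
  n <- max(M) * max(tau)
  K <- ncol(X) - n
  mm <- M
  if (grow > 0L) mm[grow] <- mm[grow] + 1L
  out <- matrix(NA_real_, K, sum(mm))
  for (i in seq_len(K)) {
    v <- c()
    for (k in seq_len(p)) {
      for (d in seq_len(mm[k]) - 1L) v <- c(v, X[k, i + d * tau[k]])
    }
    out[i, ] <- v
  }
  out
}

# multivariate sample entropy by brute force
naive_mvsampen <- function(X, M, tau, r, variant = "per_channel") {
  p <- nrow(X)
  V <- naive_cdvs(X, M, tau)
  K <- nrow(V)
  Bm <- mean(naive_match_counts(V, r) / (K - 1L))
  W <- if (variant == "per_channel") {
    do.call(rbind, lapply(seq_len(p), function(k) naive_cdvs(X, M, tau, grow = k)))
  } else {
    mm <- M + 1L
    out <- matrix(NA_real_, K, sum(mm))
    for (i in seq_len(K)) {
      v <- c()
      for (k in seq_len(p)) {
        for (d in seq_len(mm[k]) - 1L) v <- c(v, X[k, i + d * tau[k]])
      }
      out[i, ] <- v
    }
    out
  }
  Bm1 <- mean(naive_match_counts(W, r) / (nrow(W) - 1L))
  -log(Bm1 / Bm)
}

# least-squares coefficients on standardized predictors (normal equations)
ols_std_coef <- function(x, y) {
  xs <- scale(x)
  as.numeric(solve(crossprod(xs), crossprod(xs, y - mean(y))))
}

make_profile <- function(values) {
  structure(values, class = "mmse_profile", params = mmse_params(),
            channel_set = NA_character_, subject_id = NA_character_)
}

# nine-set profile list for feature assembly tests
fake_profiles <- function(ids, base = 1, jitter = 0) {
  sets <- channel_set_names()
  out <- lapply(seq_along(ids), function(i) {
    setNames(lapply(seq_along(sets), function(s) {
      make_profile(base + jitter * s + (i - 1) * 0.01 + seq(1, 0.5, length.out = 12))
    }), sets)
  })
  names(out) <- ids
  out
}
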