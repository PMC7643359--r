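#' Parameters of the multivariate multiscale sample entropy
#'
#' `M` and `tau` are the per-channel embedding dimensions and time lags;
#' scalars are recycled to the number of channels at compute time. `r` is
#' the similarity threshold on unit-variance data (Chebyshev distance),
#' `eps_max` the largest coarse-graining scale. `variant` controls how
#' delay vectors are extended from length m to m+1: `"per_channel"`
#' (default) extends by one sample of a single channel, pooling the p
#' extended sets; `"simultaneous"` appends the next sample of every
#' channel at once (length m+p).
#'
#' @param M Embedding dimension(s), positive integers (default 2).
#' @param tau Time lag(s), positive integers (default 1).
#' @param r Similarity threshold (default 0.15).
#' @param eps_max Maximum scale (default 12).
#' @param variant `"per_channel"` or `"simultaneous"`.
#' @return An object of class `mmse_params`.
#' @export
mmse_params <- function(M = 2, tau = 1, r = 0.15, eps_max = 12,
                        variant = c("per_channel", "simultaneous")) {
  variant <- match.arg(variant)
  if (!all(vapply(M, is_count, TRUE))) stopf("all embedding dimensions must be integers >= 1")
  if (!all(vapply(tau, is_count, TRUE))) stopf("all time lags must be integers >= 1")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stopf("r must be a positive scalar")
  if (!is_count(eps_max)) stopf("eps_max must be an integer >= 1")
  structure(list(M = as.integer(M), tau = as.integer(tau), r = r,
                 eps_max = as.integer(eps_max), variant = variant),
            class = "mmse_params")
}

#' @export
print.mmse_params <- function(x, ...) {
  cat(sprintf("<mmse_params> M = [%s], tau = [%s], r = %g, scales 1..%d, variant = %s\n",
              paste(x$M, collapse = ","), paste(x$tau, collapse = ","),
              x$r, x$eps_max, x$variant))
  invisible(x)
}

as_signal_matrix <- function(X) {
  if (is.numeric(X) && is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (!is.numeric(X)) stopf("signal must be numeric")
  X
}

expand_params <- function(params, p) {
  M <- params$M; tau <- params$tau
  if (length(M) == 1L) M <- rep(M, p)
  if (length(tau) == 1L) tau <- rep(tau, p)
  if (length(M) != p || length(tau) != p) {
    stopf("M and tau must have length 1 or p = %d", p)
  }
  list(M = M, tau = tau)
}

#' Normalize channels to zero mean and unit variance
#'
#' @param X Channels-by-samples numeric matrix (a vector is treated as one
#'   channel).
#' @return Matrix of the same shape, each row centered and scaled to
#'   sample standard deviation 1.
#' @export
normalize_channels <- function(X) {
  X <- as_signal_matrix(X)
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, sd)
  if (any(sdv <= 0 | !is.finite(sdv))) {
    stopf("degenerate channel: zero variance in row(s) %s",
          paste(which(sdv <= 0 | !is.finite(sdv)), collapse = ", "))
  }
  (X - mu) / sdv
}

#' Coarse-grain a series by non-overlapping averaging
#'
#' Averages consecutive non-overlapping windows of length `eps`; the
#' trailing remainder is dropped, so the output has `floor(N/eps)`
#' samples. Acts as a low-pass filter; scale 1 is the identity.
#'
#' @param x Numeric vector.
#' @param eps Scale factor (window length), integer >= 1.
#' @return Numeric vector of length `floor(length(x)/eps)`.
#' @export
coarse_grain <- function(x, eps) {
  if (!is_count(eps)) stopf("eps must be an integer >= 1")
  n <- length(x)
  if (eps > n) stopf("scale %d exceeds series length %d (empty output)", eps, n)
  if (eps == 1L) return(as.numeric(x))
  k <- floor(n / eps)
  colMeans(matrix(x[seq_len(k * eps)], nrow = eps))
}

#' Build composite delay vectors
#'
#' Concatenates, per channel k, the delay-embedded samples
#' `x_k[i], x_k[i+tau_k], ..., x_k[i+(m_k-1) tau_k]` into one row per
#' starting index i. With `n = max(M) * max(tau)` there are `N - n` rows
#' of length `m = sum(M)`.
#'
#' @param X Channels-by-samples matrix (vector = one channel).
#' @param M Embedding dimensions (scalar recycled).
#' @param tau Time lags (scalar recycled).
#' @return `(N - n) x m` numeric matrix with attributes `M`, `tau`, `n`.
#' @export
build_cdvs <- function(X, M = 2, tau = 1) {
  X <- as_signal_matrix(X)
  p <- nrow(X); N <- ncol(X)
  ex <- expand_params(list(M = M, tau = tau), p)
  M <- as.integer(ex$M); tau <- as.integer(ex$tau)
  n <- max(M) * max(tau)
  if (N <= n) stopf("insufficient samples: N = %d <= n = %d", N, n)
  K <- N - n
  cols <- vector("list", sum(M))
  jj <- 0L
  for (k in seq_len(p)) {
    for (d in seq_len(M[k]) - 1L) {
      jj <- jj + 1L
      cols[[jj]] <- X[k, seq_len(K) + d * tau[k]]
    }
  }
  V <- do.call(cbind, cols)
  attr(V, "M") <- M; attr(V, "tau") <- tau; attr(V, "n") <- n
  V
}

#' Fraction of similar vectors under the Chebyshev distance
#'
#' For each row i of `V`, counts the other rows within Chebyshev distance
#' `r` (ties at exactly `r` count; self-matches excluded) and normalizes
#' by the number of other rows. The default engine sorts by the first
#' coordinate and scans a sliding window (exact); `"blocked"` is a
#' memory-bounded vectorized R fallback with configurable block size.
#'
#' @param V Numeric matrix of vectors in rows (>= 2 rows).
#' @param r Similarity threshold, positive.
#' @param engine `"sorted"` (compiled) or `"blocked"` (vectorized R).
#' @param block_size Rows per block for the blocked engine.
#' @return List with `B_i` (per-vector fractions in `[0, 1]`) and `B`
#'   (their mean).
#' @export
similarity_fraction <- function(V, r, engine = c("sorted", "blocked"),
                                block_size = 2048L) {
  engine <- match.arg(engine)
  V <- as.matrix(V)
  if (nrow(V) < 2L) stopf("undefined similarity: need at least 2 vectors")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stopf("r must be positive")
  counts <- if (engine == "sorted") {
    cheb_match_counts(V, r)
  } else {
    blocked_match_counts(V, r, block_size)
  }
  B_i <- counts / (nrow(V) - 1L)
  list(B_i = B_i, B = mean(B_i))
}

# vectorized blocked counting: pairwise Chebyshev distances for one block
# pair at a time, memory bounded by block_size^2 doubles
blocked_match_counts <- function(V, r, block_size = 2048L) {
  n <- nrow(V); d <- ncol(V)
  block_size <- max(2L, as.integer(block_size))
  starts <- seq(1L, n, by = block_size)
  counts <- integer(n)
  for (a in starts) {
    ia <- a:min(a + block_size - 1L, n)
    for (b in starts[starts >= a]) {
      ib <- b:min(b + block_size - 1L, n)
      D <- matrix(0, length(ia), length(ib))
      for (j in seq_len(d)) {
        D <- pmax(D, abs(outer(V[ia, j], V[ib, j], "-")))
      }
      hit <- D <= r
      if (a == b) {
        hit[lower.tri(hit, diag = TRUE)] <- FALSE
        cnt <- rowSums(hit)
        counts[ia] <- counts[ia] + cnt + colSums(hit)
      } else {
        counts[ia] <- counts[ia] + rowSums(hit)
        counts[ib] <- counts[ib] + colSums(hit)
      }
    }
  }
  counts
}

#' Extend composite delay vectors to length m+1 (or m+p)
#'
#' Under `per_channel`, the embedding dimension of one channel at a time
#' is raised from `m_k` to `m_k + 1` (the extra sample sits inside that
#' channel's block of the vector), yielding `p * (N - n)` pooled vectors
#' of length m+1. Under `simultaneous`, every channel gains its next
#' sample at once, yielding `N - n` vectors of length m+p.
#'
#' @inheritParams build_cdvs
#' @param variant `"per_channel"` or `"simultaneous"`.
#' @param r Optional; when given, the similarity fraction of the extended
#'   set is also returned.
#' @return List with `vectors` (the extended matrix) and, when `r` is
#'   supplied, `B` and `B_i` from [similarity_fraction()].
#' @export
extend_cdvs <- function(X, M = 2, tau = 1,
                        variant = c("per_channel", "simultaneous"), r = NULL) {
  variant <- match.arg(variant)
  X <- as_signal_matrix(X)
  p <- nrow(X)
  ex <- expand_params(list(M = M, tau = tau), p)
  n <- max(ex$M) * max(ex$tau)
  if (ncol(X) <= n) stopf("insufficient samples: N = %d <= n = %d", ncol(X), n)
  K <- ncol(X) - n
  # per-channel embedded blocks and the next embedded sample of each channel
  blocks <- lapply(seq_len(p), function(k) {
    vapply(seq_len(ex$M[k]) - 1L, function(d) X[k, seq_len(K) + d * ex$tau[k]],
           numeric(K))
  })
  blocks <- lapply(blocks, function(b) matrix(b, nrow = K))
  nxt <- lapply(seq_len(p), function(k) {
    idx <- seq_len(K) + ex$M[k] * ex$tau[k]
    if (max(idx) > ncol(X)) stopf("insufficient samples for extension of channel %d", k)
    X[k, idx]
  })
  W <- if (variant == "simultaneous") {
    do.call(cbind, lapply(seq_len(p), function(k) cbind(blocks[[k]], nxt[[k]])))
  } else {
    do.call(rbind, lapply(seq_len(p), function(k) {
      grown <- blocks
      grown[[k]] <- cbind(grown[[k]], nxt[[k]])
      do.call(cbind, grown)
    }))
  }
  out <- list(vectors = W)
  if (!is.null(r)) {
    sf <- similarity_fraction(W, r)
    out$B <- sf$B
    out$B_i <- sf$B_i
  }
  out
}

#' Multivariate sample entropy of a multichannel series
#'
#' The negative log ratio `-ln(B^{m+1} / B^m)` of the mean similarity
#' fractions of extended versus base composite delay vectors. Input is
#' used as given (normalize beforehand; see [mmse_profile()]). When a
#' similarity count is zero the entropy is undefined and `NaN` is
#' returned with a `reason` attribute.
#'
#' @param X Channels-by-samples matrix (vector = one channel).
#' @param params An [mmse_params()] object.
#' @return Scalar entropy with attributes `Bm` and `Bm1`.
#' @export
mv_sample_entropy <- function(X, params = mmse_params()) {
  stopifnot(inherits(params, "mmse_params"))
  X <- as_signal_matrix(X)
  ex <- expand_params(params, nrow(X))
  V <- build_cdvs(X, ex$M, ex$tau)
  Bm <- similarity_fraction(V, params$r)$B
  W <- extend_cdvs(X, ex$M, ex$tau, variant = params$variant)$vectors
  Bm1 <- similarity_fraction(W, params$r)$B
  if (Bm <= 0 || Bm1 <= 0) {
    out <- NaN
    attr(out, "reason") <- if (Bm <= 0) "no template matches at length m" else
      "no template matches at length m+1"
  } else {
    out <- -log(Bm1 / Bm)
  }
  attr(out, "Bm") <- Bm
  attr(out, "Bm1") <- Bm1
  out
}

#' Multiscale entropy profile of a multichannel series
#'
#' Channels are normalized once (zero mean, unit variance) on the
#' original series, then coarse-grained at each scale `1..eps_max`, and
#' the multivariate sample entropy is computed on each coarse-grained
#' matrix with the threshold `r` held fixed. Undefined scales are carried
#' as `NaN`. A warning is issued when the coarsest series is shorter than
#' the `p * 10^max(M)` guideline.
#'
#' @param X Channels-by-samples matrix.
#' @param params An [mmse_params()] object.
#' @param normalize Normalize channels first (default `TRUE`).
#' @param channel_set Optional set name stored on the result.
#' @param subject_id Optional subject id stored on the result.
#' @return An object of class `mmse_profile`: numeric vector of length
#'   `eps_max` with attributes `params`, `channel_set`, `subject_id`.
#' @export
mmse_profile <- function(X, params = mmse_params(), normalize = TRUE,
                         channel_set = NA_character_,
                         subject_id = NA_character_) {
  stopifnot(inherits(params, "mmse_params"))
  X <- as_signal_matrix(X)
  p <- nrow(X); N <- ncol(X)
  ex <- expand_params(params, p)
  n_embed <- max(ex$M) * max(ex$tau)
  n_coarse <- floor(N / params$eps_max)
  if (n_coarse <= n_embed) {
    stopf("series too short: coarsest scale leaves %d samples (need > %d)",
          n_coarse, n_embed)
  }
  if (n_coarse < p * 10^max(ex$M)) {
    warnf("coarsest scale leaves %d samples, below the guideline of p*10^m = %d",
          n_coarse, p * 10^max(ex$M))
  }
  if (normalize) X <- normalize_channels(X)
  vals <- vapply(seq_len(params$eps_max), function(eps) {
    Xe <- do.call(rbind, lapply(seq_len(p), function(k) coarse_grain(X[k, ], eps)))
    as.numeric(mv_sample_entropy(Xe, params))
  }, numeric(1L))
  if (all(is.nan(vals))) stopf("entropy undefined at every scale")
  structure(vals, class = "mmse_profile", params = params,
            channel_set = channel_set, subject_id = subject_id,
            n_samples = N)
}

#' @export
print.mmse_profile <- function(x, digits = 4, ...) {
  cs <- attr(x, "channel_set"); sid <- attr(x, "subject_id")
  cat(sprintf("<mmse_profile> %s%sscales 1..%d\n",
              if (!is.na(sid)) paste0("subject ", sid, ", ") else "",
              if (!is.na(cs)) paste0("set ", cs, ", ") else "", length(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
plot.mmse_profile <- function(x, ...) {
  graphics::plot(seq_along(x), unclass(x), type = "b", pch = 16,
                 xlab = "scale factor", ylab = "mMSE", ...)
  invisible(x)
}

#' Per-subject profile averaged over epochs
#'
#' Element-wise mean of the per-epoch entropy profiles, skipping undefined
#' (`NaN`) entries scale by scale. The number of epochs contributing to
#' each scale is recorded in the `n_used` attribute.
#'
#' @param epochs List of channels-by-samples matrices (one per epoch).
#' @param params An [mmse_params()] object.
#' @param ... Passed to [mmse_profile()].
#' @return An `mmse_profile` averaged across epochs.
#' @export
subject_profile <- function(epochs, params = mmse_params(), ...) {
  if (!is.list(epochs) || length(epochs) == 0L) stopf("need at least one epoch")
  profs <- lapply(epochs, function(e) unclass(mmse_profile(e, params, ...)))
  mat <- do.call(rbind, profs)
  ok <- !is.nan(mat)
  n_used <- colSums(ok)
  vals <- ifelse(n_used > 0, colSums(ifelse(ok, mat, 0)) / pmax(n_used, 1L), NaN)
  dots <- list(...)
  structure(vals, class = "mmse_profile", params = params,
            channel_set = dots$channel_set %||% NA_character_,
            subject_id = dots$subject_id %||% NA_character_,
            n_epochs = length(epochs), n_used = n_used)
}
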