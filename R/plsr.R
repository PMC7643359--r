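# PLS1: univariate-response partial least squares by orthogonal-scores
# NIPALS, which for a single response coincides with SVD deflation of the
# cross-product X'y in order of decreasing covariance.

# coefficient paths for 1..ncomp components on pre-standardized X and
# centered y; shared by fitting, cross-validation and bootstrap
pls1_path <- function(Xs, yc, ncomp, tol = 1e-12) {
  n <- nrow(Xs); p <- ncol(Xs)
  ncomp_max <- min(ncomp, n - 1L, p)
  W <- P <- matrix(0, p, ncomp_max)
  Q <- numeric(ncomp_max)
  TT <- matrix(0, n, ncomp_max)
  ssy <- sum(yc^2)
  yve <- numeric(ncomp_max)
  Xc <- Xs; yr <- yc
  a <- 0L
  while (a < ncomp_max) {
    w <- crossprod(Xc, yr)
    nw <- sqrt(sum(w^2))
    if (nw < tol * max(1, ssy)) break
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < tol) break
    pl <- crossprod(Xc, t) / tt
    q <- sum(yr * t) / tt
    Xc <- Xc - t %*% t(pl)
    yr <- yr - q * t
    a <- a + 1L
    W[, a] <- w; P[, a] <- pl; Q[a] <- q; TT[, a] <- t
    yve[a] <- if (ssy > 0) 100 * q^2 * tt / ssy else 0
  }
  if (a == 0L) {
    return(list(B = matrix(0, p, 1L), ncomp = 0L, W = W[, 0, drop = FALSE],
                P = P[, 0, drop = FALSE], Q = numeric(0),
                scores = TT[, 0, drop = FALSE], yve = numeric(0)))
  }
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]
  TT <- TT[, seq_len(a), drop = FALSE]
  # B[, k]: regression coefficients using the first k components,
  # B_k = W_k (P_k' W_k)^{-1} q_k; P'W is upper triangular so the leading
  # k x k block inverts consistently with the full inverse
  Bk <- matrix(0, p, a)
  WR <- W %*% solve(crossprod(P, W))
  for (k in seq_len(a)) {
    Bk[, k] <- WR[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]
  }
  list(B = Bk, ncomp = a, W = W, P = P, Q = Q, scores = TT, yve = yve[seq_len(a)])
}

#' Fit a univariate partial least squares regression
#'
#' Predictors are centered and standardized internally (the reported
#' coefficients are on the standardized predictor scale); the response is
#' centered. Components maximize the covariance with the response and are
#' extracted by iterative deflation. The requested component count is
#' capped at the effective rank with a warning.
#'
#' @param x Numeric predictor matrix (n x p) or data frame.
#' @param y Numeric response vector.
#' @param ncomp Number of latent components (>= 1).
#' @return Object of class `plsr_fit`: coefficients (standardized scale),
#'   weights, loadings, scores, per-component percent of response
#'   variance explained (`y_variance_explained`), fitted values and
#'   residuals on the original response scale.
#' @export
fit_plsr <- function(x, y, ncomp = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("x and y sizes disagree")
  if (!is_count(ncomp)) stopf("ncomp must be a positive integer")
  if (ncomp >= nrow(x)) {
    warnf("ncomp = %d capped at n - 1 = %d", ncomp, nrow(x) - 1L)
  }
  st <- standardize_cols(x)
  ym <- mean(y)
  path <- pls1_path(st$x, y - ym, ncomp)
  if (path$ncomp < ncomp) {
    warnf("ncomp capped at effective rank %d", path$ncomp)
  }
  k <- max(path$ncomp, 1L)
  coefs <- stats::setNames(path$B[, k], colnames(x))
  fitted <- as.numeric(st$x %*% coefs) + ym
  structure(list(coefficients = coefs, ncomp = path$ncomp,
                 x_weights = path$W, x_loadings = path$P,
                 y_loadings = path$Q, scores = path$scores,
                 y_variance_explained = path$yve,
                 x_center = st$center, x_scale = st$scale, y_mean = ym,
                 fitted.values = fitted, residuals = y - fitted,
                 coef_path = path$B, n = nrow(x)),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit> %d components, n = %d, p = %d\n", x$ncomp, x$n,
              length(x$coefficients)))
  if (x$ncomp > 0) {
    cat(sprintf("  response variance explained per component: %s (total %.1f%%)\n",
                paste(sprintf("%.1f%%", x$y_variance_explained), collapse = ", "),
                sum(x$y_variance_explained)))
  }
  invisible(x)
}

#' @export
coef.plsr_fit <- function(object, ...) object$coefficients

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$x_center, "-"), 2L, object$x_scale, "/")
  as.numeric(Xs %*% object$coefficients) + object$y_mean
}

#' @export
residuals.plsr_fit <- function(object, ...) object$residuals

#' @export
fitted.plsr_fit <- function(object, ...) object$fitted.values

#' Cross-validated prediction error curve
#'
#' Root mean squared prediction error for 0 to `max_components` latent
#' components under leave-one-out (default) or seeded k-fold
#' cross-validation; the 0-component model predicts the training-fold
#' mean. Per-observation out-of-fold residuals are retained for the
#' randomization selector.
#'
#' @param x Predictor matrix; `y` response vector.
#' @param y Numeric response.
#' @param max_components Largest component count to evaluate.
#' @param folds `"loo"` or an integer number of folds.
#' @param seed Seed for k-fold assignment (ignored for LOO).
#' @return Object of class `plsr_cv`: `rmsep` (named vector over
#'   components 0..K) and `residuals` (n x (K+1) out-of-fold residuals).
#' @export
cross_validate <- function(x, y, max_components = 10L, folds = "loo",
                           seed = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 5L) stopf("need at least 5 observations for cross-validation")
  if (max_components >= n - 1L) {
    warnf("max_components capped at n - 2 = %d", n - 2L)
    max_components <- n - 2L
  }
  K <- as.integer(max_components)
  fold_id <- if (identical(folds, "loo")) {
    seq_len(n)
  } else {
    nf <- as.integer(folds)
    if (nf < 2L || nf > n) stopf("folds must be 'loo' or an integer in [2, n]")
    if (!is.null(seed)) set.seed(seed)
    sample(rep_len(seq_len(nf), n))
  }
  resid <- matrix(NA_real_, n, K + 1L)
  for (f in unique(fold_id)) {
    test <- which(fold_id == f); train <- which(fold_id != f)
    xt <- x[train, , drop = FALSE]
    sdv <- apply(xt, 2L, sd)
    keep <- sdv > 0
    st <- standardize_cols(xt[, keep, drop = FALSE])
    ym <- mean(y[train])
    path <- pls1_path(st$x, y[train] - ym, K)
    Xs <- sweep(sweep(x[test, keep, drop = FALSE], 2L, st$center, "-"),
                2L, st$scale, "/")
    resid[test, 1L] <- y[test] - ym
    if (path$ncomp > 0) {
      pred <- Xs %*% path$B + ym
      for (k in seq_len(K)) {
        kk <- min(k, path$ncomp)
        resid[test, k + 1L] <- y[test] - pred[, kk]
      }
    } else {
      resid[test, -1L] <- y[test] - ym
    }
  }
  rmsep <- sqrt(colMeans(resid^2))
  names(rmsep) <- paste0("comp", 0:K)
  structure(list(rmsep = rmsep, residuals = resid, folds = folds, n = n),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, digits = 4, ...) {
  cat("<plsr_cv> RMSEP by number of components:\n")
  print(round(x$rmsep, digits))
  invisible(x)
}

#' Select the number of latent components
#'
#' `local_min`: smallest k whose cross-validated error is below its left
#' neighbour and not above its right neighbour (the last point qualifies
#' when the curve is still decreasing there). `randomization`: van der
#' Voet's paired sign-flip test on per-observation squared prediction
#' errors — the smallest component count whose error is not significantly
#' worse than the global minimum of the curve at level `alpha`.
#'
#' @param cv A [cross_validate()] result.
#' @param method `"local_min"` or `"randomization"`.
#' @param n_perm Number of sign-flip permutations (randomization method).
#' @param alpha Significance level (randomization method).
#' @param seed Optional seed for the permutations.
#' @return Integer component count (0 = intercept-only model).
#' @export
select_ncomp <- function(cv, method = c("local_min", "randomization"),
                         n_perm = 10000L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cv, "plsr_cv"))
  method <- match.arg(method)
  rm <- as.numeric(cv$rmsep)
  K <- length(rm) - 1L
  if (K < 1L) stopf("cv curve must cover at least components 0 and 1")
  if (max(rm) - min(rm) < 1e-12) {
    warnf("flat cv curve; selecting 0 components")
    return(0L)
  }
  if (method == "local_min") {
    for (k in seq_len(K)) {
      left_drop <- rm[k + 1L] < rm[k]
      right_ok <- k == K || rm[k + 1L] <= rm[k + 2L]
      if (left_drop && right_ok) return(k)
    }
    return(0L)
  }
  # randomization: compare each candidate against the curve's global minimum
  if (!is.null(seed)) set.seed(seed)
  sq <- cv$residuals^2
  gmin <- which.min(rm) - 1L
  if (gmin == 0L) return(0L)
  for (k in 0:(gmin - 1L)) {
    d <- sq[, k + 1L] - sq[, gmin + 1L]
    obs <- mean(d)
    if (obs <= 0) return(k)
    signs <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                    nrow = n_perm)
    perm <- as.numeric(signs %*% d) / length(d)
    pval <- (1 + sum(perm >= obs)) / (n_perm + 1)
    if (pval > alpha) return(k)
  }
  gmin
}
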