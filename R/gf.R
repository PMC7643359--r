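#' Extract a single fluid-intelligence factor from a test battery
#'
#' First principal component of the correlation matrix of the test
#' scores: loadings are the test-component correlations, the eigenvalue
#' is the variance the factor explains (out of one per test), and factor
#' scores are standardized to mean 0, SD 1. The loading sign is fixed so
#' that the loadings sum positive (higher score = higher ability).
#'
#' @param battery Data frame or matrix of test scores, one column per
#'   test (>= 2 tests, >= 10 subjects, no missing values).
#' @return Object of class `gf_factor` with elements `scores`,
#'   `loadings`, `eigenvalue`, `explained_variance_pct`, `n`.
#' @export
extract_gf_factor <- function(battery) {
  X <- as.matrix(battery)
  if (!is.numeric(X)) stopf("battery must be numeric")
  if (anyNA(X)) stopf("battery has missing values")
  if (nrow(X) < 10L) stopf("need at least 10 subjects for factor extraction")
  if (ncol(X) < 2L) stopf("need at least 2 tests")
  sdv <- apply(X, 2L, sd)
  if (any(sdv <= 0)) {
    stopf("degenerate battery: constant score column(s) %s",
          paste(colnames(X)[sdv <= 0], collapse = ", "))
  }
  R <- cor(X)
  e <- eigen(R, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  lambda <- e$values[1L]
  Z <- scale(X)
  raw <- as.numeric(Z %*% v)
  scores <- as.numeric(scale(raw))
  loadings <- stats::setNames(v * sqrt(lambda), colnames(X))
  structure(list(scores = scores, loadings = loadings, eigenvalue = lambda,
                 explained_variance_pct = 100 * lambda / ncol(X),
                 n = nrow(X)),
            class = "gf_factor")
}

#' @export
print.gf_factor <- function(x, ...) {
  cat(sprintf("<gf_factor> n = %d: first factor eigenvalue %.3f (%.2f%% of variance)\n",
              x$n, x$eigenvalue, x$explained_variance_pct))
  cat("loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}
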