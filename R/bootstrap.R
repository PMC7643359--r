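#' Bootstrap relevance of PLSR coefficients
#'
#' Resamples subjects with replacement, refits the standardization and
#' the PLS regression with a fixed component count per replicate, and
#' forms percentile confidence intervals for every coefficient. A
#' predictor is flagged relevant when its interval excludes zero.
#' Replicates that draw a degenerate (zero-variance) predictor column
#' are redrawn and counted.
#'
#' Two interval types are available. `"percentile"` (default) takes the
#' plain bootstrap quantiles; under a null cohort it flags close to the
#' nominal 5 percent of predictors. `"bc"` applies Efron's median bias
#' correction before reading off the quantiles; it reproduces the
#' bias-corrected intervals reported in some PLS software, but for PLS
#' coefficients it is markedly anti-conservative (resampling inflates
#' the norm of the cross-covariance, shrinking replicate coefficients,
#' which the correction misreads as bias), so it is not the default.
#'
#' @param x Predictor matrix or data frame (n x p, n >= 10).
#' @param y Numeric response.
#' @param ncomp Fixed number of latent components.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95).
#' @param ci Interval type, `"percentile"` or `"bc"`.
#' @param seed Optional seed.
#' @return Object of class `relevance_report`: a data frame with columns
#'   `predictor`, `coefficient`, `ci_low`, `ci_high`, `se`, `relevant`,
#'   `sign`, plus attributes `n_boot`, `ncomp`, `n_redraws`,
#'   `boot_coefficients`.
#' @export
bootstrap_coefficients <- function(x, y, ncomp, n_boot = 10000L,
                                   level = 0.95,
                                   ci = c("percentile", "bc"), seed = NULL) {
  ci <- match.arg(ci)
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n < 10L) stopf("need at least 10 observations for the bootstrap")
  if (!is_count(n_boot) || n_boot < 2L) {
    stopf("insufficient replicates for percentile intervals (n_boot = %s)",
          format(n_boot))
  }
  if (!is.null(seed)) set.seed(seed)
  st <- standardize_cols(x)
  est <- pls1_coef(st$x, y - mean(y), ncomp)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot <- pls1_boot_cpp(x, y, ncomp, idx)
  n_redraws <- 0L
  bad <- which(is.na(boot[, 1L]))
  while (length(bad) > 0L) {
    n_redraws <- n_redraws + length(bad)
    if (n_redraws > 100L * n_boot) stopf("too many degenerate bootstrap draws")
    idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE),
                   nrow = length(bad))
    boot[bad, ] <- pls1_boot_cpp(x, y, ncomp, idx2)
    bad <- which(is.na(boot[, 1L]))
  }
  zal <- qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  bounds <- matrix(NA_real_, p, 2L)
  for (j in seq_len(p)) {
    probs <- if (ci == "bc") {
      prop <- (sum(boot[, j] < est[j]) + 0.5 * sum(boot[, j] == est[j])) / n_boot
      prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
      pnorm(2 * qnorm(prop) + zal)
    } else {
      pnorm(zal)
    }
    bounds[j, ] <- quantile(boot[, j], probs, names = FALSE, type = 7)
  }
  rep <- data.frame(predictor = colnames(x) %||% paste0("x", seq_len(p)),
                    coefficient = as.numeric(est),
                    ci_low = bounds[, 1L], ci_high = bounds[, 2L],
                    se = apply(boot, 2L, sd),
                    stringsAsFactors = FALSE)
  rep$relevant <- rep$ci_low > 0 | rep$ci_high < 0
  rep$sign <- ifelse(rep$coefficient > 0, "+", ifelse(rep$coefficient < 0, "-", "0"))
  structure(rep, class = c("relevance_report", "data.frame"),
            n_boot = n_boot, ncomp = ncomp, level = level, ci_type = ci,
            n_redraws = n_redraws, boot_coefficients = boot)
}

# fast column SDs
colSds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colMeans(x^2) - mu^2, 0) * n / (n - 1))
}

# coefficients only, for hot loops
pls1_coef <- function(Xs, yc, ncomp) {
  path <- pls1_path(Xs, yc, ncomp)
  path$B[, max(path$ncomp, 1L)]
}

#' @export
print.relevance_report <- function(x, digits = 3, max_rows = 20L, ...) {
  cat(sprintf("<relevance_report> %d predictors, %d relevant (%d bootstrap replicates, %d components)\n",
              nrow(x), sum(x$relevant), attr(x, "n_boot"), attr(x, "ncomp")))
  shown <- x[x$relevant, , drop = FALSE]
  if (nrow(shown) == 0L) shown <- head(as.data.frame(x), max_rows)
  df <- as.data.frame(shown)
  df$boot_coefficients <- NULL
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# order: relevant-positive by descending coefficient, then
# relevant-negative by descending magnitude, then the rest
sort_relevance <- function(rep) {
  pos <- rep$coefficient > 0
  key <- ifelse(rep$relevant & pos, 0L, ifelse(rep$relevant & !pos, 1L, 2L))
  rep[order(key, -abs(rep$coefficient)), , drop = FALSE]
}
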