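#' Relate complexity features to fluid intelligence by PLSR
#'
#' The front-door fitting function: filters the feature table by group,
#' selects the number of latent components from the cross-validated error
#' curve (first local minimum and randomization test are both computed),
#' fits the partial least squares regression of the gf score on the
#' complexity predictors, and bootstraps bias-corrected confidence
#' intervals to flag relevant predictors.
#'
#' @param formula Model formula; the default `gf ~ .` regresses the gf
#'   column on all predictor columns (`subject_id` and `sex` are never
#'   used as predictors).
#' @param data A feature table: `subject_id`, `sex` (`"M"`/`"W"`), `gf`
#'   and numeric predictor columns.
#' @param group `"all"`, `"men"` or `"women"`.
#' @param ncomp `"auto"` (use `selector`) or a fixed component count.
#' @param selector Component selector used when `ncomp = "auto"`:
#'   `"local_min"` or `"randomization"`.
#' @param max_components Largest component count scanned by CV.
#' @param n_boot Bootstrap replicates for the relevance intervals.
#' @param ci Bootstrap interval type, `"percentile"` (default) or `"bc"`
#'   (see [bootstrap_coefficients()]).
#' @param n_perm Sign-flip permutations for the randomization selector.
#' @param alpha Level of the randomization selector.
#' @param folds `"loo"` or an integer fold count for the CV curve.
#' @param exclude Character vector of subject ids to drop before fitting
#'   (no automatic outlier removal is performed).
#' @param seed Seed governing CV fold draws, the randomization test and
#'   the bootstrap.
#' @return Object of class `complexity_plsr` with elements `model`
#'   ([fit_plsr()] result), `cv`, `ncomp`, `ncomp_local_min`,
#'   `ncomp_randomization`, `relevance` (sorted report), `group`, `n`.
#' @examples
#' tab <- generate_feature_table(cohort_spec(n_subjects = 40, seed = 7))
#' fit <- complexity_plsr(gf ~ ., tab, ncomp = 1, n_boot = 50, seed = 1)
#' coef(fit)[1:3]
#' @export
complexity_plsr <- function(formula = gf ~ ., data,
                            group = c("all", "men", "women"),
                            ncomp = "auto",
                            selector = c("local_min", "randomization"),
                            max_components = 10L, n_boot = 10000L,
                            n_perm = 10000L, alpha = 0.05, folds = "loo",
                            ci = c("percentile", "bc"),
                            exclude = NULL, seed = NULL) {
  group <- match.arg(group)
  selector <- match.arg(selector)
  if (!all(data$sex %in% c("M", "W"))) {
    stopf("schema error: unknown sex codes %s",
          paste(unique(setdiff(data$sex, c("M", "W"))), collapse = ", "))
  }
  keep <- switch(group, all = rep(TRUE, nrow(data)),
                 men = data$sex == "M", women = data$sex == "W")
  if (!is.null(exclude)) keep <- keep & !(data$subject_id %in% exclude)
  sub <- data[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("empty group '%s'", group)
  if (nrow(sub) < 10L) stopf("group '%s' has n = %d < 10", group, nrow(sub))

  mf_vars <- setdiff(names(sub), c("subject_id", "sex"))
  mdata <- sub[, mf_vars, drop = FALSE]
  tf <- stats::terms(formula, data = mdata)
  resp <- all.vars(formula)[attr(tf, "response")]
  preds <- gsub("^`|`$", "", attr(tf, "term.labels"))
  y <- as.numeric(mdata[[resp]])
  x <- as.matrix(mdata[, preds, drop = FALSE])

  if (!is.null(seed)) set.seed(seed)
  cv_seed <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  cv <- cross_validate(x, y, max_components = max_components, folds = folds,
                       seed = cv_seed)
  sel_seed <- if (is.null(seed)) NULL else derive_seed(seed, 2L)
  k_local <- select_ncomp(cv, "local_min")
  k_rand <- select_ncomp(cv, "randomization", n_perm = n_perm, alpha = alpha,
                         seed = sel_seed)
  k <- if (identical(ncomp, "auto")) {
    if (selector == "local_min") k_local else k_rand
  } else {
    as.integer(ncomp)
  }
  k_fit <- max(k, 1L)
  model <- fit_plsr(x, y, ncomp = k_fit)
  boot_seed <- if (is.null(seed)) NULL else derive_seed(seed, 3L)
  rel <- bootstrap_coefficients(x, y, ncomp = k_fit, n_boot = n_boot,
                                ci = ci, seed = boot_seed)
  at <- attributes(rel)
  rel_sorted <- sort_relevance(as.data.frame(rel))
  rownames(rel_sorted) <- NULL
  class(rel_sorted) <- c("relevance_report", "data.frame")
  attr(rel_sorted, "n_boot") <- at$n_boot
  attr(rel_sorted, "ncomp") <- at$ncomp
  attr(rel_sorted, "level") <- at$level
  attr(rel_sorted, "n_redraws") <- at$n_redraws

  structure(list(model = model, cv = cv, ncomp = k,
                 ncomp_local_min = k_local, ncomp_randomization = k_rand,
                 relevance = rel_sorted, group = group, n = nrow(sub),
                 predictors = preds, response = resp,
                 subject_id = sub$subject_id,
                 call = match.call()),
            class = "complexity_plsr")
}

#' Group analysis over a feature table
#'
#' Convenience wrapper around [complexity_plsr()] matching the pipeline
#' stage interface: takes a validated feature table and a group label and
#' returns the fitted model plus the sorted relevance report.
#'
#' @param table Feature table (see [validate_feature_table()]).
#' @param group `"all"`, `"men"` or `"women"`.
#' @param ... Passed on to [complexity_plsr()].
#' @return A `complexity_plsr` object.
#' @export
run_group_analysis <- function(table, group = c("all", "men", "women"), ...) {
  complexity_plsr(gf ~ ., data = table, group = match.arg(group), ...)
}

#' @export
print.complexity_plsr <- function(x, ...) {
  cat(sprintf("Complexity ~ gf PLS regression (%s sample, n = %d)\n",
              x$group, x$n))
  cat(sprintf("  components: %d used (local minimum: %d, randomization test: %d)\n",
              x$ncomp, x$ncomp_local_min, x$ncomp_randomization))
  if (x$model$ncomp > 0) {
    cat(sprintf("  response variance explained: %s (total %.0f%%)\n",
                paste(sprintf("%.0f%%", x$model$y_variance_explained),
                      collapse = ", "),
                sum(x$model$y_variance_explained)))
  }
  cat(sprintf("  relevant predictors: %d of %d\n", sum(x$relevance$relevant),
              nrow(x$relevance)))
  invisible(x)
}

#' @export
summary.complexity_plsr <- function(object, ...) {
  structure(list(fit = object, relevance = object$relevance),
            class = "summary.complexity_plsr")
}

#' @export
print.summary.complexity_plsr <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$relevance)
  invisible(x)
}

#' @export
coef.complexity_plsr <- function(object, ...) coef(object$model)

#' @export
predict.complexity_plsr <- function(object, newdata, ...) {
  if (missing(newdata)) return(predict(object$model))
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object$predictors, drop = FALSE])
  }
  predict(object$model, newdata)
}

#' @export
residuals.complexity_plsr <- function(object, ...) residuals(object$model)

#' @export
fitted.complexity_plsr <- function(object, ...) fitted(object$model)

#' Plot a fitted complexity regression
#'
#' Left panel: cross-validated error against the number of components
#' with the selected counts marked. Right panel: coefficients and
#' bootstrap intervals of the relevant predictors.
#'
#' @param x A `complexity_plsr` object.
#' @param ... Further graphical arguments (ignored).
#' @export
plot.complexity_plsr <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4, 2, 1))
  on.exit(graphics::par(op))
  comps <- seq_along(x$cv$rmsep) - 1L
  graphics::plot(comps, x$cv$rmsep, type = "b", pch = 16,
                 xlab = "components", ylab = "CV RMSEP", main = "CV curve")
  graphics::abline(v = x$ncomp, lty = 2)
  rel <- x$relevance[x$relevance$relevant, , drop = FALSE]
  if (nrow(rel) == 0L) rel <- head(as.data.frame(x$relevance), 10L)
  idx <- seq_len(nrow(rel))
  graphics::plot(rel$coefficient, rev(idx), xlim = range(c(rel$ci_low, rel$ci_high, 0)),
                 pch = 16, yaxt = "n", xlab = "coefficient (standardized X)",
                 ylab = "", main = "relevant predictors")
  graphics::segments(rel$ci_low, rev(idx), rel$ci_high, rev(idx))
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = rev(idx), labels = rel$predictor, las = 2, cex.axis = 0.6)
  invisible(x)
}
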