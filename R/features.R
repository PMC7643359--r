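.feature_kinds <- c("AUC", "MaxSlope", "AvgEnt")
.set_pairs <- list(c("F", "P"), c("FL", "PL"), c("FR", "PR"),
                   c("FL", "FR"), c("PL", "PR"), c("ML", "MR"))

#' Names of the 45 complexity predictors
#'
#' 27 per-set features `<feat>_<set>` (feat in AUC, MaxSlope, AvgEnt over
#' the nine channel sets) followed by 18 between-set differences
#' `<feat>_<A>-<B>` for the pairs F-P, FL-PL, FR-PR, FL-FR, PL-PR, ML-MR.
#'
#' @return Character vector of length 45.
#' @export
feature_names <- function() {
  sets <- channel_set_names()
  base <- as.vector(vapply(.feature_kinds, function(f) paste0(f, "_", sets),
                           character(length(sets))))
  diffs <- as.vector(vapply(.feature_kinds, function(f) {
    vapply(.set_pairs, function(pr) paste0(f, "_", pr[1], "-", pr[2]), "")
  }, character(length(.set_pairs))))
  c(base, diffs)
}

profile_values <- function(profile) {
  v <- as.numeric(profile)
  if (anyNA(v) || any(is.nan(v))) stopf("feature undefined: profile has undefined entries")
  v
}

#' Area under the entropy profile
#'
#' Trapezoidal area over the scale index with unit spacing:
#' `sum((v[e] + v[e+1]) / 2)`. Summarizes total complexity across scales.
#'
#' @param profile An [mmse_profile()] or numeric vector (length >= 2).
#' @return Scalar area.
#' @export
auc <- function(profile) {
  v <- profile_values(profile)
  if (length(v) < 2L) stopf("profile must have at least 2 scales")
  sum((v[-length(v)] + v[-1L]) / 2)
}

#' Maximum fine-scale slope of the entropy profile
#'
#' Signed maximum of `(v[j] - v[i]) / (j - i)` over all pairs
#' `1 <= i < j <= 4` of the first four scales: the steepest rise (or, if
#' the profile falls throughout, least steep fall) at fine scales.
#'
#' @param profile An [mmse_profile()] or numeric vector (length >= 4).
#' @return Scalar slope (signed).
#' @export
max_slope <- function(profile) {
  v <- profile_values(profile)
  if (length(v) < 4L) stopf("profile must have at least 4 scales")
  v <- v[1:4]
  best <- -Inf
  for (i in 1:3) for (j in (i + 1):4) {
    best <- max(best, (v[j] - v[i]) / (j - i))
  }
  best
}

#' Mean coarse-scale entropy
#'
#' Mean of scales 9 to 12 of the profile: the baseline complexity level
#' at coarse scales.
#'
#' @param profile An [mmse_profile()] or numeric vector (length >= 12).
#' @return Scalar mean.
#' @export
avg_ent <- function(profile) {
  v <- profile_values(profile)
  if (length(v) < 12L) stopf("profile must have at least 12 scales")
  mean(v[9:12])
}

#' Assemble the per-subject feature table
#'
#' Reduces each subject's nine per-set profiles to AUC, MaxSlope and
#' AvgEnt, adds the 18 between-set differences (first-named minus
#' second-named set), and binds subject id, sex and the gf score.
#' Subjects missing any set are excluded with a message.
#'
#' @param profiles Named list: `profiles[[subject]][[set]]` is a profile
#'   (numeric vector of >= 12 scales) for each of the nine sets.
#' @param gf Named numeric vector of gf scores (names = subject ids), or
#'   unnamed in the order of `profiles`.
#' @param sex Character vector (`"M"`/`"W"`), named like `gf` or in order.
#' @return A `data.frame` with columns `subject_id`, `sex`, `gf` and the
#'   45 predictors of [feature_names()], rows sorted by subject id.
#' @export
assemble_features <- function(profiles, gf, sex) {
  subjects <- names(profiles)
  if (is.null(subjects)) stopf("profiles must be a named list (subject ids)")
  gf <- if (is.null(names(gf))) stats::setNames(gf, subjects) else gf
  sex <- if (is.null(names(sex))) stats::setNames(sex, subjects) else sex
  sets <- channel_set_names()
  rows <- list()
  for (s in subjects) {
    have <- sets %in% names(profiles[[s]])
    if (!all(have)) {
      message(sprintf("subject %s excluded: missing set(s) %s", s,
                      paste(sets[!have], collapse = ", ")))
      next
    }
    feats <- numeric(0)
    bad <- FALSE
    for (kind in .feature_kinds) {
      fn <- switch(kind, AUC = auc, MaxSlope = max_slope, AvgEnt = avg_ent)
      vals <- vapply(sets, function(st) {
        tryCatch(fn(profiles[[s]][[st]]), error = function(e) NA_real_)
      }, numeric(1L))
      feats <- c(feats, stats::setNames(vals, paste0(kind, "_", sets)))
      bad <- bad || anyNA(vals)
    }
    if (bad) {
      message(sprintf("subject %s excluded: undefined profile feature(s)", s))
      next
    }
    for (kind in .feature_kinds) {
      for (pr in .set_pairs) {
        nm <- paste0(kind, "_", pr[1], "-", pr[2])
        feats[nm] <- feats[paste0(kind, "_", pr[1])] -
          feats[paste0(kind, "_", pr[2])]
      }
    }
    rows[[s]] <- feats
  }
  if (length(rows) == 0L) stopf("no complete subjects to assemble")
  mat <- do.call(rbind, rows)[, feature_names(), drop = FALSE]
  ids <- sort(names(rows))
  mat <- mat[ids, , drop = FALSE]
  out <- data.frame(subject_id = ids, sex = as.character(sex[ids]),
                    gf = as.numeric(gf[ids]), check.names = FALSE,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat, check.names = FALSE))
}
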