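test_that("single-factor extraction matches eigenvalue arithmetic", {
  set.seed(40)
  base <- rnorm(50)
  same <- as.data.frame(replicate(6, base))
  res <- extract_gf_factor(same)
  expect_equal(res$explained_variance_pct, 100)
  expect_equal(res$eigenvalue, 6)

  # independent columns: identity correlation, top eigenvalue ~ 1
  ind <- as.data.frame(matrix(rnorm(10000 * 6), ncol = 6))
  res_ind <- extract_gf_factor(ind)
  expect_equal(res_ind$eigenvalue, 1, tolerance = 0.05)
  expect_equal(res_ind$explained_variance_pct, 100 / 6, tolerance = 5)

  # scores standardized
  set.seed(41)
  bat <- generate_test_scores(rnorm(119), seed = 42)
  r <- extract_gf_factor(bat)
  expect_equal(mean(r$scores), 0, tolerance = 1e-10)
  expect_equal(sd(r$scores), 1, tolerance = 1e-10)
  expect_equal(r$explained_variance_pct, 100 * r$eigenvalue / 6)

  const <- bat; const$RAPM <- 5
  expect_error(extract_gf_factor(const), "degenerate battery")
  expect_error(extract_gf_factor(bat[1:5, ]), "at least 10")
})

test_that("full-component PLSR equals the least-squares oracle", {
  set.seed(43)
  n <- 50; p <- 7
  X <- matrix(rnorm(n * p), n); colnames(X) <- paste0("v", 1:p)
  y <- X %*% runif(p, -1, 1) + rnorm(n)
  fit <- fit_plsr(X, y, ncomp = p)
  expect_equal(unname(coef(fit)), ols_std_coef(X, y), tolerance = 1e-8)
  expect_equal(fitted(fit), as.numeric(fitted(lm(y ~ X))), tolerance = 1e-8)
})

test_that("one-predictor PLS1 collapses to simple regression", {
  set.seed(44)
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "x"))
  y <- 0.7 * x[, 1] + rnorm(40)
  fit <- fit_plsr(x, y, 1)
  expect_equal(unname(coef(fit)), ols_std_coef(x, y), tolerance = 1e-12)
  expect_equal(predict(fit, x), fitted(fit))
})

test_that("PLSR agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(45)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n); colnames(X) <- paste0("v", 1:p)
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(n)
  ours <- fit_plsr(X, y, 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  pred_mo <- predict(mo, X)$predict[, , 3]
  expect_equal(fitted(ours), as.numeric(pred_mo), tolerance = 1e-10)
})

test_that("response variance explained is per component and bounded", {
  set.seed(46)
  X <- matrix(rnorm(80 * 5), 80); colnames(X) <- paste0("v", 1:5)
  y <- X[, 2] + rnorm(80, sd = 0.5)
  fit <- fit_plsr(X, y, 3)
  expect_true(all(fit$y_variance_explained >= 0))
  expect_lte(sum(fit$y_variance_explained), 100)
  # y orthogonal to X in sample: nothing explained
  y0 <- residuals(lm(rnorm(80) ~ X))
  fit0 <- suppressWarnings(fit_plsr(X, y0, 2))
  expect_equal(sum(fit0$y_variance_explained), 0, tolerance = 1e-8)
})

test_that("cross-validation is reproducible and caps the component count", {
  set.seed(47)
  X <- matrix(rnorm(40 * 6), 40); colnames(X) <- paste0("v", 1:6)
  y <- X[, 1] + rnorm(40)
  cv1 <- cross_validate(X, y, 4)
  cv2 <- cross_validate(X, y, 4)
  expect_identical(cv1$rmsep, cv2$rmsep)
  expect_length(cv1$rmsep, 5L)
  expect_warning(cross_validate(X[1:8, ], y[1:8], 20), "capped")
  kf <- cross_validate(X, y, 3, folds = 5, seed = 1)
  kf2 <- cross_validate(X, y, 3, folds = 5, seed = 1)
  expect_identical(kf$rmsep, kf2$rmsep)
})

test_that("component selectors follow their curve definitions", {
  fake_cv <- function(rmsep, n = 30) {
    structure(list(rmsep = setNames(rmsep, paste0("comp", seq_along(rmsep) - 1)),
                   residuals = matrix(rnorm(n * length(rmsep)), n), n = n),
              class = "plsr_cv")
  }
  expect_equal(select_ncomp(fake_cv(c(5, 3, 4, 2)), "local_min"), 1L)
  expect_equal(select_ncomp(fake_cv(9:1), "local_min"), 8L)
  expect_equal(select_ncomp(fake_cv(c(2, 3, 4)), "local_min"), 0L)
  expect_warning(k <- select_ncomp(fake_cv(rep(1, 5)), "local_min"), "flat")
  expect_equal(k, 0L)

  # randomization agrees with local-min on curves with one sharp minimum
  set.seed(48)
  for (i in 1:8) {
    n <- 40
    kmin <- sample(1:4, 1)
    scales <- 0.5 + abs(seq_len(6) - 1 - kmin)  # V-shaped, sharp min at kmin
    base <- abs(rnorm(n)) + 0.2
    resid <- outer(base, scales)
    cv_syn <- structure(list(
      rmsep = setNames(sqrt(colMeans(resid^2)), paste0("comp", 0:5)),
      residuals = resid, n = n), class = "plsr_cv")
    expect_equal(select_ncomp(cv_syn, "local_min"), kmin)
    expect_equal(select_ncomp(cv_syn, "randomization", n_perm = 500, seed = i),
                 kmin)
  }
})

test_that("bootstrap relevance is seed-stable and flags a strong effect", {
  set.seed(49)
  tab <- generate_feature_table(cohort_spec(n_subjects = 60,
                                            true_beta = c(AvgEnt_P = 0.8),
                                            seed = 50))
  X <- as.matrix(tab[, feature_names()])
  r1 <- bootstrap_coefficients(X, tab$gf, 1, n_boot = 400, seed = 7)
  r2 <- bootstrap_coefficients(X, tab$gf, 1, n_boot = 400, seed = 7)
  expect_identical(r1$ci_low, r2$ci_low)
  row <- r1[r1$predictor == "AvgEnt_P", ]
  expect_true(row$relevant)
  expect_identical(row$sign, "+")
  expect_true(all(r1$ci_low < r1$ci_high))
  expect_error(bootstrap_coefficients(X, tab$gf, 1, n_boot = 1),
               "insufficient replicates")
})

test_that("group analyses filter by sex and validate codes", {
  set.seed(51)
  tab <- generate_feature_table(cohort_spec(n_subjects = 40, seed = 52))
  fit <- run_group_analysis(tab, "all", ncomp = 1, n_boot = 100, n_perm = 200,
                            seed = 1)
  expect_s3_class(fit, "complexity_plsr")
  expect_equal(nrow(fit$relevance), 45L)
  expect_equal(fit$n, 40L)

  men <- run_group_analysis(tab, "men", ncomp = 1, n_boot = 100, n_perm = 200,
                            seed = 1)
  expect_equal(men$n, sum(tab$sex == "M"))

  women_only <- tab[tab$sex == "W", ]
  expect_error(run_group_analysis(women_only, "men"), "empty group")
  bad <- tab; bad$sex[3] <- "X"
  expect_error(run_group_analysis(bad, "all"), "schema error")
})

test_that("a constructed difference-feature effect is recovered end to end", {
  set.seed(53)
  tab <- generate_feature_table(cohort_spec(
    n_subjects = 119, true_beta = c(`AvgEnt_FL-FR` = 0.6), noise_sd = 1,
    seed = 54))
  fit <- run_group_analysis(tab, "all", ncomp = 1, n_boot = 500, seed = 2)
  row <- fit$relevance[fit$relevance$predictor == "AvgEnt_FL-FR", ]
  expect_true(row$relevant)
  expect_identical(row$sign, "+")
  # report sorted: relevant positives first, by descending coefficient
  expect_identical(fit$relevance$predictor[1], "AvgEnt_FL-FR")
})

test_that("sex-stratified fits are indistinguishable without a sex effect", {
  # sex has no generative role, so men's and women's coefficient
  # distributions should overlap; pool three cohorts and compare
  cm <- cw <- c()
  for (i in 1:3) {
    tab <- generate_feature_table(cohort_spec(
      n_subjects = 119, true_beta = c(AUC_P = 0.4), seed = 800 + i))
    fm <- run_group_analysis(tab, "men", ncomp = 1, n_boot = 50, seed = i)
    fw <- run_group_analysis(tab, "women", ncomp = 1, n_boot = 50, seed = i)
    cm <- c(cm, coef(fm))
    cw <- c(cw, coef(fw))
  }
  expect_gt(suppressWarnings(ks.test(cm, cw)$p.value), 0.005)
  expect_lt(abs(mean(cm) - mean(cw)), 0.05)
})

test_that("exclusion lists drop subjects before fitting", {
  set.seed(55)
  tab <- generate_feature_table(cohort_spec(n_subjects = 30, seed = 56))
  fit <- complexity_plsr(gf ~ ., tab, ncomp = 1, n_boot = 50, seed = 1,
                         exclude = c("S001", "S002"))
  expect_equal(fit$n, 28L)
  expect_false(any(c("S001", "S002") %in% fit$subject_id))
})
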