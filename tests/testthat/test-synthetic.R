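test_that("signal generation is deterministic and validates its spec", {
  sp <- signal_spec(n_channels = 3, n_samples = 512, seed = 11)
  a <- generate_subject_signal(sp)
  b <- generate_subject_signal(sp)
  expect_identical(a$data, b$data)
  expect_true(all(is.finite(a$data)))
  expect_equal(dim(a$data), c(3L, 512L))
  c2 <- generate_subject_signal(signal_spec(3, 512, seed = 12))
  expect_false(identical(a$data, c2$data))

  expect_error(signal_spec(n_channels = 0), "invalid spec")
  expect_error(signal_spec(n_samples = -5), "invalid spec")
  expect_error(signal_spec(pink_weight = 1.2), "invalid spec")
  expect_error(signal_spec(alpha_amp = -1), "invalid spec")
})

test_that("pure white signals have the nominal variance and entropy decay", {
  vars <- sapply(1:20, function(i) {
    sp <- signal_spec(2, 2048, pink_weight = 0, alpha_amp = 0,
                      amplitude_uv = 10, seed = 100 + i)
    mean(apply(generate_subject_signal(sp)$data, 1, var))
  })
  expect_equal(mean(vars), 100, tolerance = 0.05)

  # fine-scale entropy above coarse-scale entropy for temporally white noise
  d <- sapply(1:8, function(i) {
    sp <- signal_spec(4, 4096, pink_weight = 0, alpha_amp = 0, seed = 200 + i)
    pr <- suppressWarnings(mmse_profile(generate_subject_signal(sp)$data,
                                        mmse_params()))
    as.numeric(pr)[1] - as.numeric(pr)[12]
  })
  expect_gt(mean(d), 0)
})

test_that("pink-dominated signals keep a flatter coarse-scale tail", {
  # full 40 s epochs: the coarse-scale estimate needs the study epoch length
  tails <- sapply(1:6, function(i) {
    tail_of <- function(pw, seed) {
      sp <- signal_spec(4, 10240, pink_weight = pw, alpha_amp = 0, seed = seed)
      pr <- mmse_profile(generate_subject_signal(sp)$data, mmse_params())
      as.numeric(pr)[12]
    }
    tail_of(1, 300 + i) - tail_of(0, 400 + i)
  })
  expect_gt(mean(tails), 0)
})

test_that("feature-level cohorts carry the requested ground truth", {
  spec <- cohort_spec(n_subjects = 119, seed = 21)
  tab <- generate_feature_table(spec)
  expect_equal(nrow(tab), 119L)
  expect_equal(names(tab), c("subject_id", "sex", "gf", feature_names()))
  expect_identical(tab, generate_feature_table(spec))
  # null cohort: all features uncorrelated with gf
  r <- sapply(feature_names(), function(f) cor(tab[[f]], tab$gf))
  expect_lt(max(abs(r)), 3 / sqrt(119))

  # a single nonzero effect is recovered by the OLS oracle within 3 SE
  spec2 <- cohort_spec(n_subjects = 119, true_beta = c(AUC_F = 0.8),
                       noise_sd = 1, seed = 22)
  tab2 <- generate_feature_table(spec2)
  fit <- lm(tab2$gf ~ tab2$AUC_F)
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 0.8), 3 * est["Std. Error"])

  expect_error(cohort_spec(n_subjects = 2), "invalid spec")
  expect_error(cohort_spec(noise_sd = -1), "invalid spec")
  expect_error(cohort_spec(feature_cov = diag(10)), "invalid spec")
  ncov <- diag(45); ncov[1, 1] <- -2
  expect_error(cohort_spec(feature_cov = ncov), "positive semidefinite")
  expect_error(cohort_spec(true_beta = c(NotAFeature = 1)), "unknown feature")
})

test_that("test batteries have the designed single-factor strength", {
  set.seed(23)
  gf <- rnorm(4000)
  # near-degenerate: loadings 0.99 -> first factor explains ~98%
  hi <- generate_test_scores(gf, loadings = rep(0.99, 6), seed = 1)
  ev_hi <- eigen(cor(hi), symmetric = TRUE, only.values = TRUE)$values[1]
  expect_equal(100 * ev_hi / 6, 98, tolerance = 0.02)

  # equal loadings 0.786: implied correlation matrix ll' + diag(1 - l^2)
  # has top eigenvalue 1 + 5 * 0.786^2 = 4.089, i.e. 68.1% explained
  lam <- rep(0.786, 6)
  R_implied <- lam %o% lam; diag(R_implied) <- 1
  ev_implied <- eigen(R_implied, symmetric = TRUE, only.values = TRUE)$values[1]
  expect_equal(100 * ev_implied / 6, 68.15, tolerance = 0.001)
  mid <- generate_test_scores(gf, loadings = lam, seed = 2)
  ev_mid <- eigen(cor(mid), symmetric = TRUE, only.values = TRUE)$values[1]
  expect_equal(ev_mid, ev_implied, tolerance = 0.03)

  # default loadings are calibrated to a 61.8%-variance first factor
  def <- generate_test_scores(gf, seed = 3)
  ev_def <- eigen(cor(def), symmetric = TRUE, only.values = TRUE)$values[1]
  expect_equal(100 * ev_def / 6, 61.8, tolerance = 0.02)

  expect_error(generate_test_scores(gf, loadings = rep(1.2, 6)), "invalid spec")
})

test_that("factor scores recover the generating ability at n = 119", {
  cors <- sapply(1:5, function(i) {
    set.seed(500 + i)
    gf <- rnorm(119)
    battery <- generate_test_scores(gf, seed = 600 + i)
    cor(extract_gf_factor(battery)$scores, gf)
  })
  expect_true(all(cors > 0.9))
})

test_that("signal-level cohorts tie gf to the pink weight", {
  specs <- lapply(1:6, function(i) {
    signal_spec(2, 256, pink_weight = (i - 1) / 5, seed = 700 + i)
  })
  names(specs) <- sprintf("S%02d", 1:6)
  coh <- generate_end_to_end_cohort(specs)
  expect_equal(names(coh$recordings), names(specs))
  pw <- sapply(specs, function(s) s$pink_weight)
  expect_equal(cor(coh$gf, pw), 1, tolerance = 1e-12)
  coh2 <- generate_end_to_end_cohort(specs)
  expect_identical(coh$recordings[[3]]$data, coh2$recordings[[3]]$data)

  expect_error(generate_end_to_end_cohort(list()), "consistency error")
  expect_error(generate_end_to_end_cohort(specs, gf = c(bad = 1)),
               "consistency error")
})
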