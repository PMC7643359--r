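test_that("channel normalization centers, scales, and is idempotent", {
  set.seed(1)
  X <- matrix(rnorm(300, mean = 5, sd = 3), nrow = 3)
  Z <- normalize_channels(X)
  expect_equal(rowMeans(Z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(Z, 1, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(normalize_channels(Z), Z, tolerance = 1e-12)
  expect_error(normalize_channels(rbind(X[1, ], rep(2, 100))),
               "degenerate channel")
})

test_that("coarse graining averages disjoint windows and composes", {
  expect_identical(coarse_grain(1:6, 1), as.numeric(1:6))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  expect_error(coarse_grain(1:3, 5), "exceeds")
  set.seed(2)
  x <- rnorm(120)
  expect_equal(coarse_grain(x, 6), coarse_grain(coarse_grain(x, 2), 3))
  expect_equal(coarse_grain(x, 6), coarse_grain(coarse_grain(x, 3), 2))
})

test_that("composite delay vectors follow the embedding worked example", {
  set.seed(3)
  X <- matrix(rnorm(20), nrow = 2)  # p = 2, N = 10
  V <- build_cdvs(X, M = c(3, 2), tau = c(2, 1))
  expect_equal(dim(V), c(4L, 5L))  # N - n = 10 - 3*2 = 4 rows, m = 3+2 = 5
  # row i = (x1[i], x1[i+2], x1[i+4], x2[i], x2[i+1])
  expect_equal(V[2, ], c(X[1, 2], X[1, 4], X[1, 6], X[2, 2], X[2, 3]))
  expect_equal(V, naive_cdvs(X, c(3, 2), c(2, 1)), ignore_attr = TRUE)

  V1 <- build_cdvs(matrix(rnorm(5), 1), M = 2, tau = 1)
  expect_equal(dim(V1), c(3L, 2L))
  Vc <- build_cdvs(matrix(1, 2, 10), M = 2, tau = 1)
  expect_true(all(Vc == Vc[1, 1]))
  expect_error(build_cdvs(matrix(rnorm(8), 2), M = c(3, 2), tau = c(2, 1)),
               "insufficient samples")
})

test_that("extended vectors have length m+1 (pooled) or m+p (simultaneous)", {
  set.seed(4)
  X <- matrix(rnorm(20), nrow = 2)
  sim <- extend_cdvs(X, c(3, 2), c(2, 1), "simultaneous")$vectors
  expect_equal(dim(sim), c(4L, 7L))   # m + p = 5 + 2
  pc <- extend_cdvs(X, c(3, 2), c(2, 1), "per_channel")$vectors
  expect_equal(dim(pc), c(8L, 6L))    # p*(N-n) = 8 pooled rows, m + 1 = 6
  expect_equal(pc[1:4, ], naive_cdvs(X, c(3, 2), c(2, 1), grow = 1L))
  expect_equal(pc[5:8, ], naive_cdvs(X, c(3, 2), c(2, 1), grow = 2L))
  # degenerate equivalence at p = 1
  x <- matrix(rnorm(30), 1)
  a <- extend_cdvs(x, 2, 1, "per_channel")$vectors
  b <- extend_cdvs(x, 2, 1, "simultaneous")$vectors
  expect_equal(a, b)
})

test_that("similarity fractions match hand enumeration and bounds", {
  same <- matrix(1, 5, 3)
  sf <- similarity_fraction(same, r = 0.1)
  expect_equal(sf$B_i, rep(1, 5))
  expect_equal(sf$B, 1)
  far <- matrix(c(0, 10, 20, 30), ncol = 1)
  expect_equal(similarity_fraction(far, r = 0.15)$B, 0)
  # V = {0, 0.1, 0.3}, r = 0.15: pairs (1,2) match, (1,3) and (2,3) do not
  sf3 <- similarity_fraction(matrix(c(0, 0.1, 0.3), ncol = 1), r = 0.15)
  expect_equal(sf3$B_i, c(1 / 2, 1 / 2, 0))
  expect_equal(sf3$B, 1 / 3)
  expect_error(similarity_fraction(matrix(1, 1, 2), 0.1), "at least 2")
  # ties at exactly r count as matches
  tie <- similarity_fraction(matrix(c(0, 0.15), ncol = 1), r = 0.15)
  expect_equal(tie$B, 1)
})

test_that("sorted and blocked engines agree exactly with the naive oracle", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    d <- sample(1:6, 1)
    V <- matrix(rnorm(n * d), n, d)
    r <- runif(1, 0.05, 0.5)
    oracle <- naive_match_counts(V, r)
    sorted <- similarity_fraction(V, r, engine = "sorted")
    blocked <- similarity_fraction(V, r, engine = "blocked",
                                   block_size = sample(c(4, 16, 128), 1))
    expect_identical(sorted$B_i, oracle / (n - 1))
    expect_identical(blocked$B_i, sorted$B_i)
  }
})

test_that("multivariate sample entropy equals the brute-force oracle", {
  set.seed(6)
  for (i in 1:12) {
    p <- sample(1:3, 1)
    N <- sample(30:60, 1)
    X <- matrix(rnorm(p * N), p, N)
    for (variant in c("per_channel", "simultaneous")) {
      got <- as.numeric(mv_sample_entropy(X, mmse_params(r = 0.5,
                                                         variant = variant)))
      want <- naive_mvsampen(X, rep(2L, p), rep(1L, p), 0.5, variant)
      if (is.finite(want)) {
        expect_equal(got, want, tolerance = 1e-14)
      } else {
        expect_true(is.nan(got))  # zero match count flagged, not +/-Inf
      }
    }
  }
})

test_that("entropy handles constants and undefined counts", {
  expect_equal(as.numeric(mv_sample_entropy(matrix(0.7, 2, 40))), 0)
  # pairwise-far vectors: no matches at length m -> flagged undefined
  x <- matrix(seq(0, 100, length.out = 30), 1)
  v <- mv_sample_entropy(x, mmse_params(r = 0.01))
  expect_true(is.nan(as.numeric(v)))
  expect_match(attr(v, "reason"), "no template matches")
})

test_that("univariate entropy approaches the iid Gaussian closed form", {
  set.seed(7)
  x <- matrix(rnorm(40000), 1)
  got <- as.numeric(mv_sample_entropy(x))
  expect_equal(got, -log(2 * pnorm(0.15 / sqrt(2)) - 1), tolerance = 0.05)
})

test_that("profiles have one value per scale and respect trivial cases", {
  set.seed(8)
  X <- matrix(rnorm(2 * 3000), 2)
  pr <- suppressWarnings(mmse_profile(X, mmse_params(eps_max = 12)))
  expect_s3_class(pr, "mmse_profile")
  expect_length(pr, 12L)
  one <- suppressWarnings(mmse_profile(X, mmse_params(eps_max = 1)))
  expect_equal(as.numeric(one),
               as.numeric(mv_sample_entropy(normalize_channels(X))))
  expect_warning(mmse_profile(matrix(rnorm(2 * 500), 2), mmse_params()),
                 "guideline")
})

test_that("profiles are invariant to affine rescaling of channels", {
  set.seed(9)
  X <- matrix(rnorm(3 * 2400), 3)
  X2 <- X
  X2[2, ] <- 37 * X2[2, ] - 11
  p1 <- suppressWarnings(mmse_profile(X, mmse_params(r = 0.5, eps_max = 6)))
  p2 <- suppressWarnings(mmse_profile(X2, mmse_params(r = 0.5, eps_max = 6)))
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-12)
})

test_that("per-channel entropy is non-negative when defined", {
  set.seed(10)
  for (i in 1:10) {
    p <- sample(1:3, 1)
    X <- matrix(rnorm(p * 400), p)
    v <- as.numeric(mv_sample_entropy(X, mmse_params(r = 0.8)))
    if (!is.nan(v)) expect_gte(v, 0)
  }
})

test_that("subject profiles average per-epoch profiles scale-wise", {
  set.seed(11)
  e1 <- matrix(rnorm(2 * 1200), 2)
  e2 <- matrix(rnorm(2 * 1200), 2)
  prm <- mmse_params(eps_max = 4)
  single <- subject_profile(list(e1), prm)
  expect_equal(as.numeric(single), as.numeric(mmse_profile(e1, prm)))
  twice <- subject_profile(list(e1, e1), prm)
  expect_equal(as.numeric(twice), as.numeric(single))
  both <- subject_profile(list(e1, e2), prm)
  manual <- (as.numeric(mmse_profile(e1, prm)) +
             as.numeric(mmse_profile(e2, prm))) / 2
  expect_equal(as.numeric(both), manual)
  expect_error(subject_profile(list()), "at least one epoch")
})
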