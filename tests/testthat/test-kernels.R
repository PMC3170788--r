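test_that("feature distances reproduce hand-computed values", {
  expect_equal(feature_distance(c(1, 0), c(0, 1), "chi2"), 2.0)
  expect_equal(feature_distance(c(1, 2), c(3, 1), "L1"), 3.0)
  expect_equal(feature_distance(c(0, 3), c(4, 0), "L2"), 5.0)
  set.seed(1)
  x <- runif(10)
  expect_equal(feature_distance(x, x, "chi2"), 0)
  expect_error(feature_distance(1:3, 1:4, "L1"), "lengths")
  expect_error(feature_distance(c(-1, 1), c(1, 1), "chi2"), "nonnegative")
})

test_that("all three metrics match a loop oracle on random pairs", {
  set.seed(2)
  for (metric in c("L1", "L2", "chi2")) {
    for (i in 1:50) {
      x <- runif(20)
      y <- runif(20)
      expect_lt(abs(feature_distance(x, y, metric) -
                      loop_distance(x, y, metric)), 1e-12)
    }
  }
})

test_that("metric axioms hold: symmetry, non-negativity, identity of indiscernibles", {
  set.seed(3)
  for (metric in c("L1", "L2", "chi2")) {
    for (i in 1:20) {
      x <- runif(15)
      y <- runif(15)
      dxy <- feature_distance(x, y, metric)
      expect_gte(dxy, 0)
      expect_equal(dxy, feature_distance(y, x, metric), tolerance = 1e-12)
      expect_equal(feature_distance(x, x, metric), 0)
    }
    # d(x, y) = 0 iff x = y (nonnegative vectors)
    x <- runif(10)
    y <- x
    y[4] <- y[4] + 0.5
    expect_gt(feature_distance(x, y, metric), 0)
  }
})

test_that("pairwise and cross distances match per-pair calls", {
  set.seed(4)
  f <- matrix(runif(10 * 12), 10, 12)
  for (metric in c("L1", "L2", "chi2")) {
    D <- pairwise_distances(f, metric)
    expect_equal(D, t(D))
    expect_equal(diag(D), numeric(10))
    for (i in 1:10) for (j in 1:10) {
      expect_lt(abs(D[i, j] - feature_distance(f[i, ], f[j, ], metric)),
                1e-12)
    }
    Dx <- cross_distances(f[1:3, ], f[4:10, ], metric)
    for (i in 1:3) for (j in 1:7) {
      expect_lt(abs(Dx[i, j] - feature_distance(f[i, ], f[j + 3, ], metric)),
                1e-12)
    }
  }
  expect_equal(pairwise_distances(f[1, , drop = FALSE]),
               matrix(0, 1, 1))
  expect_equal(pairwise_distances(f[c(1, 1), ]), matrix(0, 2, 2))
})

test_that("gamma is the mean over all ordered pairs, with degenerate fallback", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(compute_gamma(D2), 1.5)
  expect_warning(g0 <- compute_gamma(matrix(0, 4, 4)), "gamma")
  expect_equal(g0, 1)
  set.seed(5)
  A <- matrix(runif(400), 20, 20)
  D <- A + t(A)
  diag(D) <- 0
  s <- 0
  for (i in 1:20) for (j in 1:20) s <- s + D[i, j]
  expect_lt(abs(compute_gamma(D) - s / 400), 1e-12)
  expect_error(compute_gamma(matrix(0, 2, 3)), "square")
})

test_that("rbf kernel is exp(-S/gamma) elementwise", {
  expect_equal(rbf_kernel(matrix(0, 2, 2), 1), matrix(1, 2, 2))
  expect_equal(rbf_kernel(matrix(2.5, 1, 1), 2.5)[1, 1], exp(-1))
  set.seed(6)
  S <- matrix(runif(30, 0, 5), 5, 6)
  K <- rbf_kernel(S, 1.7)
  for (i in 1:5) for (j in 1:6) {
    expect_lt(abs(K[i, j] - exp(-S[i, j] / 1.7)), 1e-12)
  }
  expect_error(rbf_kernel(S, 0), "positive")
})

test_that("jkec fusion is the elementwise mean, with an optional weighted hook", {
  K1 <- matrix(0.2, 3, 3)
  K2 <- matrix(0.6, 3, 3)
  expect_equal(jkec_combine(list(K1)), K1)
  expect_equal(jkec_combine(list(K1, K2)), matrix(0.4, 3, 3))
  set.seed(7)
  ks <- lapply(1:5, function(i) matrix(runif(16), 4, 4))
  fused <- jkec_combine(ks)
  for (i in 1:4) for (j in 1:4) {
    expect_lt(abs(fused[i, j] -
                    mean(vapply(ks, function(k) k[i, j], numeric(1)))),
              1e-12)
  }
  expect_equal(jkec_combine(ks[1:2], weights = c(1, 0)), ks[[1]])
  expect_error(jkec_combine(list(K1, matrix(0, 2, 2))), "shapes")
  expect_error(jkec_combine(ks[1:2], weights = c(0.4, 0.4)), "sum to 1")
})

test_that("equal-contribution identity: mean(S/gamma) over ordered pairs is exactly 1", {
  set.seed(8)
  for (metric in c("L1", "L2", "chi2")) {
    for (rep in 1:3) {
      f <- matrix(runif(sample(5:25, 1) * 12), ncol = 12)
      D <- pairwise_distances(f, metric)
      g <- compute_gamma(D)
      expect_lt(abs(mean(D / g) - 1), 1e-9)
    }
  }
})

test_that("kernels lie in (0,1], train kernels are symmetric with unit diagonal, fused inherits both", {
  set.seed(9)
  feats <- list(a = matrix(runif(8 * 10), 8, 10),
                b = matrix(runif(8 * 4), 8, 4))
  kernels <- lapply(feats, function(f) {
    D <- pairwise_distances(f, "chi2")
    rbf_kernel(D, compute_gamma(D))
  })
  fused <- jkec_combine(kernels)
  for (K in c(kernels, list(fused))) {
    expect_true(all(K > 0 & K <= 1))
    expect_equal(K, t(K))
    expect_equal(diag(K), rep(1, 8))
  }
})

test_that("L1/L2 kernels are invariant to rescaling a feature (gamma absorbs scale)", {
  set.seed(10)
  f <- matrix(runif(12 * 6), 12, 6)
  for (metric in c("L1", "L2")) {
    D1 <- pairwise_distances(f, metric)
    K1 <- rbf_kernel(D1, compute_gamma(D1))
    D2 <- pairwise_distances(7.3 * f, metric)
    K2 <- rbf_kernel(D2, compute_gamma(D2))
    expect_equal(K1, K2, tolerance = 1e-9)
  }
})

test_that("kernel matrices round-trip bit-exactly through TSV", {
  set.seed(11)
  K <- matrix(runif(25), 5, 5,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:5)))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(K, path)
  back <- read_matrix_tsv(path)
  expect_identical(unname(back), unname(K))
  expect_identical(dimnames(back), dimnames(K))
})
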