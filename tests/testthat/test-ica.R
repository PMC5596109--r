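test_that("whitening round-trips, normalizes covariance, and reduces rank", {
  set.seed(1)
  X <- matrix(rnorm(6 * 500), 6) * (1:6)
  wh <- center_whiten(X, 6)
  # population covariance of output is the identity
  C <- tcrossprod(wh$z) / ncol(X)
  expect_lt(max(abs(C - diag(6))), 1e-8)
  expect_true(all(abs(rowMeans(wh$z)) < 1e-10))
  # subspace round-trip at full rank
  Xr <- wh$dewhitening %*% wh$z + wh$row_means
  expect_lt(max(abs(Xr - X)), 1e-8)
  # rank-2 data requested at order 5 falls back with a warning
  X2 <- matrix(rnorm(2 * 300), 2)
  X5 <- matrix(rnorm(10), 5, 2) %*% X2  # 5 channels, rank 2
  expect_warning(wh2 <- center_whiten(X5, 5), "rank")
  expect_equal(wh2$order, 2)
})

test_that("fastica separates uniform mixtures as well as the rotation oracle", {
  set.seed(42)
  for (rep in 1:3) {
    S <- matrix(runif(2 * 20000, -1, 1), 2)
    A <- matrix(rnorm(4), 2)
    X <- A %*% S
    m <- fastica(X, 2, seed = rep)
    expect_true(m$converged)
    expect_lt(amari_index(m$unmixing %*% A), 0.05)
    W_oracle <- rotation_oracle(X)
    expect_lt(amari_index(m$unmixing %*% solve(W_oracle)), 0.02)
  }
})

test_that("fastica output is uncorrelated, unit variance, and seed-deterministic", {
  maps <- sparse_maps(4, 2000, seed = 3)
  X <- matrix(rnorm(16), 4) %*% maps
  m <- fastica(X, 4, seed = 5)
  C <- tcrossprod(m$S) / ncol(m$S)
  expect_lt(max(abs(C - diag(4))), 1e-6)
  m2 <- fastica(X, 4, seed = 5)
  expect_identical(m$S, m2$S)
  # permuting input channels leaves sources invariant up to order/sign
  perm <- c(3, 1, 4, 2)
  mp <- fastica(X[perm, ], 4, seed = 5)
  mr <- match_components(mp$S, m$S)
  expect_true(all(abs(mr$correlations) > 0.999))
})

test_that("already-independent standardized inputs are returned up to permutation/sign", {
  maps <- fmica:::zscore_rows(sparse_maps(3, 3000, seed = 8))
  m <- fastica(maps, 3, seed = 2)
  mr <- match_components(m$S, maps)
  expect_true(all(abs(mr$correlations) > 0.99))
})

test_that("Gaussian-only data is flagged non-identifiable", {
  set.seed(9)
  X <- matrix(rnorm(3 * 5000), 3)
  m <- suppressWarnings(fastica(X, 3, seed = 1, max_iter = 200))
  kurts <- apply(m$S, 1, sample_kurtosis)
  expect_true(!m$converged || all(abs(kurts) < 0.2))
})

test_that("Laplace order estimation finds planted ranks", {
  set.seed(14)
  # 5 strong components + white noise
  A <- matrix(rnorm(30 * 5), 30)
  S <- matrix(rnorm(5 * 500), 5)
  X <- A %*% S + 0.1 * matrix(rnorm(30 * 500), 30)
  est <- estimate_order_laplace(X, 20)
  expect_s3_class(est, "order_estimate")
  expect_equal(est$chosen, 5)
  expect_true(all(is.finite(est$scores)))
  # pure white noise: evidence maximized at the smallest candidate
  N <- matrix(rnorm(10 * 4000), 10)
  estn <- estimate_order_laplace(N, 9)
  expect_equal(estn$chosen, 1)
  # wide data handled through the smaller covariance
  Xw <- t(X)
  estw <- estimate_order_laplace(Xw, 20)
  expect_equal(estw$chosen, 5)
})

test_that("mean order uses round-half-up", {
  expect_equal(mean_order(c(13, 13, 13)), 13)
  expect_equal(mean_order(c(10, 11)), 11)
  expect_equal(mean_order(c(20, 22, 25)), 22)
  expect_error(mean_order(integer(0)), "non-empty")
})

test_that("ICASSO stability selects the true order on noisy separable data", {
  maps <- sparse_maps(5, 2000, seed = 6)
  set.seed(10)
  X <- matrix(rnorm(20 * 5), 20) %*% maps + 2 * matrix(rnorm(20 * 2000), 20)
  est <- suppressWarnings(icasso_select(X, 3, 8, n_runs = 8, seed = 4))
  expect_equal(est$candidates, 3:8)
  expect_equal(est$chosen, 5)
  expect_gt(est$scores$mean[est$scores$order == 5], 0.9)
  # the selection rule prefers the stability maximum
  expect_gte(est$scores$mean[est$scores$order == est$chosen] + 1e-6,
             max(est$scores$mean, na.rm = TRUE))
})

test_that("duplicate decompositions are perfectly stable", {
  # orthogonal zero-mean components duplicated across "runs" give Iq = 1
  t <- seq(0, 2 * pi, length.out = 400)[-400]
  comp <- rbind(cos(t), sin(t), cos(2 * t))
  pooled <- rbind(comp, comp)
  iq <- fmica:::cluster_stability(pooled, 3)
  expect_equal(iq, rep(1, 3), tolerance = 1e-10)
})
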