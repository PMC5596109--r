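test_that("spatial correlation matches direct arithmetic", {
  set.seed(3)
  m <- rnorm(50)
  expect_equal(spatial_correlation(m, m), 1)
  expect_equal(spatial_correlation(m, -m), -1)
  # hand-computed 4-voxel pair
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  expect_equal(spatial_correlation(x, y), 6.5 / sqrt(5 * 8.75))
  expect_error(spatial_correlation(rep(1, 4), y), "constant")
})

test_that("matching recovers permutations and sign flips exactly", {
  maps <- sparse_maps(5, 1000, seed = 17)
  perm <- c(4, 2, 5, 1, 3)
  signs <- c(1, -1, 1, -1, -1)
  est <- diag(signs) %*% maps[perm, ]
  mr <- match_components(est, maps)
  expect_equal(mr$assignment, order(perm))
  expect_equal(abs(mr$correlations), rep(1, 5), tolerance = 1e-12)
  expect_equal(sign(mr$correlations), signs[order(perm)])
  expect_length(mr$unmatched_templates, 0)
})

test_that("greedy and exhaustive assignments agree on well-separated instances", {
  for (s in 1:10) {
    maps <- sparse_maps(5, 800, seed = s)
    set.seed(s + 100)
    est <- maps[sample(5), ] * sample(c(-1, 1), 5, TRUE) +
      0.05 * matrix(rnorm(5 * 800), 5)
    g <- match_components(est, maps, method = "greedy")
    o <- match_components(est, maps, method = "optimal")
    expect_equal(g$assignment, o$assignment)
  }
})

test_that("partial matching lists unmatched templates", {
  maps <- sparse_maps(3, 600, seed = 23)
  mr <- match_components(maps[1:2, ], maps)
  expect_equal(sum(is.na(mr$assignment)), 1)
  expect_length(mr$unmatched_templates, 1)
})

test_that("recovery report is internally consistent", {
  maps <- sparse_maps(4, 900, seed = 29)
  rep0 <- recovery_report(maps, maps)
  expect_equal(rep0$per_source, rep(1, 4))
  expect_equal(rep0$sd, 0)
  set.seed(30)
  est <- maps + 0.3 * matrix(rnorm(4 * 900), 4)
  rep1 <- recovery_report(est, maps)
  expect_equal(rep1$mean, mean(rep1$per_source))
  expect_equal(rep1$sd, sd(rep1$per_source))
})

test_that("the two-sample contrast matches the closed-form t statistic", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 4, 6, 9)
  res <- contrast_ttest(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 4)
  expect_equal(res$t, (mean(a) - mean(b)) / se)
  expect_equal(res$mean_a, 2.5)
  # identical groups: t = 0, p = 1
  res0 <- contrast_ttest(a, a)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(contrast_ttest(rep(1, 3), rep(2, 3)), "zero variance")
  expect_error(contrast_ttest(1, c(1, 2)), "at least 2")
})
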