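test_that("z-scoring matches the closed form and is affine-invariant", {
  s <- zscore_map(c(1, 2, 3))
  expect_equal(s$z_values, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  set.seed(1)
  m <- rnorm(200, 5, 3)
  z <- zscore_map(m)$z_values
  expect_lt(abs(mean(z)), 1e-8)
  expect_lt(abs(fmica:::pop_sd(z) - 1), 1e-8)
  z2 <- zscore_map(2.5 * m + 7)$z_values
  expect_equal(z, z2, tolerance = 1e-10)
  expect_error(zscore_map(rep(4, 10)), "constant")
})

test_that("cluster-size control keeps only sufficiently large blobs", {
  g <- 12L
  img <- matrix(0, g, g)
  img[2:5, 2:4] <- 5      # 12-voxel blob
  img[9:12, 10] <- 5      # 4-voxel line, grows to 5 with the corner voxel
  img[8, 11] <- 5         # 8-connected to the line: total 5 voxels
  spm <- structure(list(z_values = as.vector(img), shape = c(g, g)),
                   class = "spm_map")
  bfn <- threshold_clusters(spm, z_threshold = 2, min_cluster = 10)
  expect_equal(bfn$n_voxels, 12)
  expect_equal(bfn$cluster_sizes, 12)
  expect_true(all(bfn$z_values[as.vector(img) == 0] == 0))
  # min_cluster = 1 degenerates to a simple threshold
  bfn1 <- threshold_clusters(spm, z_threshold = 2, min_cluster = 1)
  expect_equal(bfn1$n_voxels, 17)
  expect_equal(sort(bfn1$cluster_sizes, decreasing = TRUE), c(12, 5))
  # defaults are z = 2.0 and 10 voxels
  expect_equal(formals(threshold_clusters)$z_threshold, 2.0)
  expect_equal(eval(formals(threshold_clusters)$min_cluster), 10L)
})

test_that("labeling matches the flood-fill oracle on random grids", {
  set.seed(33)
  for (i in 1:25) {
    keep <- runif(400) < runif(1, 0.2, 0.6)
    ours <- fmica:::label_clusters(keep, c(20L, 20L))
    oracle <- flood_fill_labels(keep, c(20L, 20L))
    expect_true(same_partition(ours, oracle))
  }
})

test_that("thresholding is monotone and idempotent", {
  set.seed(44)
  z <- rnorm(900, 0, 1.5)
  spm <- structure(list(z_values = z, shape = c(30L, 30L)), class = "spm_map")
  prev <- Inf
  for (zt in c(1, 1.5, 2, 2.5)) {
    n <- threshold_clusters(spm, zt, 5)$n_voxels
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (mc in c(1, 5, 10, 20)) {
    n <- threshold_clusters(spm, 1.2, mc)$n_voxels
    expect_lte(n, prev)
    prev <- n
  }
  b1 <- threshold_clusters(spm, 1.5, 8)
  b2 <- threshold_clusters(structure(list(z_values = b1$z_values,
                                          shape = b1$shape),
                                     class = "spm_map"), 1.5, 8)
  expect_equal(b2$z_values, b1$z_values)
  expect_equal(b2$n_voxels, b1$n_voxels)
  # empty result is valid and flagged
  be <- threshold_clusters(spm, 99, 10)
  expect_true(be$empty)
  expect_equal(be$n_voxels, 0)
})

test_that("3D volumes are labeled with full diagonal connectivity", {
  shp <- c(5L, 5L, 5L)
  z <- numeric(prod(shp))
  # two voxels touching only at a corner: one 26-connected cluster
  z[1] <- 3                                   # (1,1,1)
  z[1 + 1 + 5 + 25] <- 3                      # (2,2,2)
  bfn <- threshold_clusters(z, 2, 1, shape = shp)
  expect_equal(length(bfn$cluster_sizes), 1)
  expect_equal(bfn$cluster_sizes, 2)
})
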