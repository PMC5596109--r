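test_that("closeness is sign-invariant negative absolute correlation", {
  set.seed(2)
  r <- rnorm(100)
  expect_equal(closeness(r, r), -1)
  expect_equal(closeness(-r, r), -1)
  # constructed orthogonal pair
  y <- c(1, -1, 1, -1)
  r2 <- c(1, 1, -1, -1)
  expect_equal(closeness(y, r2), 0)
  expect_error(closeness(rep(1, 5), rnorm(5)), "constant")
  expect_error(closeness(rnorm(5), rnorm(6)), "equal length")
})

test_that("reference thresholding keeps only the activated tail", {
  # z-scores of (0,0,0,10) are (-0.577, -0.577, -0.577, 1.732): one survivor
  rs <- make_references(matrix(c(0, 0, 0, 10), 1), z_ref = 1.0)
  expect_equal(sum(rs$references != 0), 1)
  expect_equal(rs$references[1, 4], 1.5 / sqrt(0.75))
  # z_ref = -Inf keeps the whole z-scored map
  m <- matrix(rnorm(50), 2)
  rs2 <- make_references(m, z_ref = -Inf)
  expect_equal(rs2$references, fmica:::zscore_rows(m))
  # default threshold is 1.0
  expect_equal(formals(make_references)$z_ref, 1.0)
  # a map entirely below threshold errors with the component named
  expect_error(make_references(rbind(rnorm(20), rnorm(20) - 100), z_ref = 50),
               "1, 2")
})

test_that("constrained extraction recovers referenced sources from mixtures", {
  maps <- sparse_maps(5, 3000, seed = 12)
  set.seed(13)
  A <- matrix(rnorm(25), 5)
  X <- A %*% maps
  refs <- make_references(maps, z_ref = 1.0)
  ex <- icar_extract(X, refs, seed = 1)
  for (j in 1:5) {
    expect_gt(abs(cor(ex$maps[j, ], maps[j, ])), 0.99)
    expect_equal(mean(ex$maps[j, ]^2), 1, tolerance = 1e-6)
  }
  expect_false(any(ex$constraint_violated))
  # single-reference extraction matches the referenced map, not the others
  one <- icar_extract(X, refs$references[3, , drop = FALSE], seed = 2)
  cors <- abs(apply(maps, 1, cor, y = one$maps[1, ]))
  expect_equal(which.max(cors), 3L)
  expect_gt(cors[3], 0.99)
})

test_that("an unrelated reference raises the constraint-violated flag", {
  maps <- sparse_maps(4, 2000, seed = 21)
  set.seed(22)
  X <- matrix(rnorm(16), 4) %*% maps
  stranger <- matrix(rnorm(2000), 1)  # uncorrelated with every mixture row
  ex <- icar_extract(X, stranger, xi = -0.5, seed = 3)
  expect_true(ex$constraint_violated[1])
})

test_that("reference permutation permutes the outputs identically", {
  maps <- sparse_maps(4, 2500, seed = 31)
  set.seed(32)
  X <- matrix(rnorm(16), 4) %*% maps
  refs <- make_references(maps, 1.0)
  perm <- c(2, 4, 1, 3)
  ex1 <- icar_extract(X, refs$references, seed = 5)
  ex2 <- icar_extract(X, refs$references[perm, ], seed = 5)
  for (j in seq_along(perm))
    expect_gt(abs(cor(ex2$maps[j, ], ex1$maps[perm[j], ])), 0.9999)
})

test_that("loosening the closeness bound never lowers the attained contrast", {
  nl <- fmica:::ica_nonlinearity("tanh")
  J <- function(y) (mean(nl$G(y)) - nl$EG_gauss)^2
  maps <- sparse_maps(4, 2500, seed = 41)
  set.seed(43)
  X <- matrix(rnorm(16), 4) %*% maps
  ref <- make_references(maps, 1.0)$references[2, , drop = FALSE]
  xis <- c(-0.95, -0.8, -0.5, -0.2)
  js <- vapply(xis, function(x) {
    ex <- icar_extract(X, ref, xi = x, seed = 4)
    J(ex$maps[1, ])
  }, numeric(1))
  expect_true(all(diff(js) >= -1e-9))
})
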