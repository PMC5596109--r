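# Shared fixture builders: everything generated in code, scaled for speed.

# Small study conditions: 24x24 grid, 4 sources, 48 TRs, one task source.
small_config <- function(n_subjects = 3L, seed = 7L,
                         task_sources = list(list(source = 4L, task_ratio = 4,
                                                  unique_amp = 0.25)), ...) {
  sim_config(n_subjects = n_subjects, grid_side = 24L, n_sources = 4L,
             n_timepoints = 48L, tr = 2, block_on = 16, block_off = 16,
             n_blocks = 2L, task_sources = task_sources, seed = seed, ...)
}

# Super-Gaussian spatial "maps" with strong sparse structure (blocks of
# activation), good for unambiguous ICA recovery.
sparse_maps <- function(n, V, seed = 1L) {
  set.seed(seed)
  t(vapply(seq_len(n), function(k) {
    m <- rnorm(V, 0, 0.1)
    on <- seq.int((k - 1) * floor(V / n) + 1, length.out = floor(V / (2 * n)))
    m[on] <- m[on] + rexp(length(on), rate = 0.5)
    m
  }, numeric(V)))
}

sample_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

# Independent flood-fill connected-components labeling (BFS, 8-connectivity)
# used as the oracle for cluster labeling.
flood_fill_labels <- function(keep, shape) {
  g1 <- shape[1]; g2 <- shape[2]
  img <- matrix(keep, g1, g2)
  labels <- matrix(0L, g1, g2)
  cur <- 0L
  for (i in seq_len(g1)) for (j in seq_len(g2)) {
    if (!img[i, j] || labels[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    labels[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || ni > g1 || nj < 1 || nj > g2) next
        if (img[ni, nj] && labels[ni, nj] == 0L) {
          labels[ni, nj] <- cur
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  as.integer(labels)
}

# Same-partition check for two labelings (labels may be numbered differently).
same_partition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  on <- a > 0L
  length(unique(paste(a[on], b[on]))) == length(unique(a[on])) &&
    length(unique(a[on])) == length(unique(b[on]))
}

# Brute-force oracle for 2-source ICA: grid search over the 1-parameter
# rotation of the whitened data maximizing total |kurtosis|.
rotation_oracle <- function(X, n_grid = 720L) {
  wh <- center_whiten(X, 2)
  Z <- wh$z
  thetas <- seq(0, pi / 2, length.out = n_grid)
  score <- vapply(thetas, function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    Y <- R %*% Z
    abs(sample_kurtosis(Y[1, ])) + abs(sample_kurtosis(Y[2, ]))
  }, numeric(1))
  th <- thetas[which.max(score)]
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  R %*% wh$whitening
}
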