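#' Center and whiten a channels x samples matrix
#'
#' Rows are channels (time points or feature maps), columns are samples
#' (voxels). PCA-reduces to \code{order} dimensions; the output rows have zero
#' mean, unit variance and are mutually uncorrelated (population convention).
#' If the data have fewer non-degenerate directions than requested, the order
#' is reduced with a warning.
#'
#' @param data numeric matrix, channels in rows.
#' @param order target dimensionality (<= nrow(data)).
#' @param eig_tol relative eigenvalue cutoff defining numerical rank.
#' @return list with \code{z} (order x samples whitened data), \code{whitening}
#'   (order x channels), \code{dewhitening} (channels x order),
#'   \code{row_means}, \code{order}, \code{eigenvalues}.
#' @export
center_whiten <- function(data, order, eig_tol = 1e-10) {
  data <- as.matrix(data)
  assert_that(all(is.finite(data)), "data must be finite")
  assert_that(order >= 1 && order <= nrow(data),
              "order must be between 1 and nrow(data)")
  mu <- rowMeans(data)
  xc <- data - mu
  n <- ncol(xc)
  C <- tcrossprod(xc) / n
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > eig_tol * max(e$values)
  rank <- sum(keep)
  if (rank < order) {
    warning("requested order ", order, " exceeds numerical rank ", rank,
            "; reducing")
    order <- rank
  }
  vals <- e$values[seq_len(order)]
  U <- e$vectors[, seq_len(order), drop = FALSE]
  whitening <- diag(1 / sqrt(vals), order) %*% t(U)
  dewhitening <- U %*% diag(sqrt(vals), order)
  list(z = whitening %*% xc, whitening = whitening, dewhitening = dewhitening,
       row_means = mu, order = order, eigenvalues = e$values)
}

# Contrast nonlinearities for negentropy maximisation.
# tanh: G(u) = log cosh(u); pow3: G(u) = u^4/4.
ica_nonlinearity <- function(name = c("tanh", "pow3")) {
  name <- match.arg(name)
  if (name == "tanh")
    list(g = function(u) tanh(u), dg = function(u) 1 - tanh(u)^2,
         G = function(u) log(cosh(u)), EG_gauss = 0.3745672)
  else
    list(g = function(u) u^3, dg = function(u) 3 * u^2,
         G = function(u) u^4 / 4, EG_gauss = 0.75)
}

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

# Orient each row of S (and matching columns of A) so its skewness is
# positive; fall back to the largest-|value| sample being positive.
fix_signs <- function(S, A = NULL, W = NULL) {
  for (k in seq_len(nrow(S))) {
    s <- S[k, ]
    sk <- mean((s - mean(s))^3)
    flip <- if (abs(sk) > 1e-12) sk < 0 else s[which.max(abs(s))] < 0
    if (flip) {
      S[k, ] <- -S[k, ]
      if (!is.null(A)) A[, k] <- -A[, k]
      if (!is.null(W)) W[k, ] <- -W[k, ]
    }
  }
  list(S = S, A = A, W = W)
}

#' Fixed-point (FastICA) decomposition with symmetric decorrelation
#'
#' Maximises the negentropy contrast over an orthogonal rotation of the
#' whitened data. Components are sign-fixed to positive skewness and ordered
#' by descending variance explained in the original space; deterministic given
#' \code{seed}.
#'
#' @param data channels x samples matrix.
#' @param order number of components.
#' @param seed integer seed for the random orthogonal initialisation.
#' @param nonlinearity "tanh" (log cosh; default) or "pow3" (kurtosis).
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on max |<w_new, w_old>| deviation from 1.
#' @return an \code{unmixing_model}: list with \code{S} (order x samples,
#'   unit-variance uncorrelated sources), \code{W} (order x order rotation in
#'   whitened space), \code{unmixing} (order x channels composite, so
#'   \code{S = unmixing \%*\% (data - row_means)}), \code{mixing} (channels x
#'   order), \code{whitening}, \code{dewhitening}, \code{row_means},
#'   \code{n_iterations}, \code{converged}, \code{seed}.
#' @export
fastica <- function(data, order, seed = 1L, nonlinearity = "tanh",
                    max_iter = 1000L, tol = 1e-6) {
  nl <- ica_nonlinearity(nonlinearity)
  wh <- center_whiten(data, order)
  order <- wh$order
  Z <- wh$z
  n <- ncol(Z)
  W <- with_seed(seed, matrix(rnorm(order * order), order))
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- W %*% Z
    GY <- nl$g(Y)
    W1 <- tcrossprod(GY, Z) / n - diag(rowMeans(nl$dg(Y)), order) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fastica did not converge in ", max_iter, " iterations")
  S <- W %*% Z
  A <- wh$dewhitening %*% t(W)      # data ~ row_means + A %*% S
  unmix <- W %*% wh$whitening
  # order by variance explained in the original space (S rows unit variance)
  expl <- colSums(A^2)
  ord <- order(expl, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]; A <- A[, ord, drop = FALSE]
  W <- W[ord, , drop = FALSE]; unmix <- unmix[ord, , drop = FALSE]
  fs <- fix_signs(S, A, unmix)
  structure(list(S = fs$S, W = W, unmixing = fs$W, mixing = fs$A,
                 whitening = wh$whitening, dewhitening = wh$dewhitening,
                 row_means = wh$row_means, n_iterations = it,
                 converged = converged, seed = seed,
                 variance_explained = expl[ord]),
            class = "unmixing_model")
}

#' @export
print.unmixing_model <- function(x, ...) {
  cat(sprintf("<unmixing_model: %d components x %d samples, %d iterations, %s>\n",
              nrow(x$S), ncol(x$S), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Model order by Laplace-approximation evidence (Minka)
#'
#' Computes the Laplace-approximation log-evidence of a probabilistic PCA
#' model for each candidate dimensionality on the eigenspectrum of the sample
#' covariance, working on the smaller-dimension covariance when channels
#' exceed samples. The chosen order maximises the evidence.
#'
#' @param data channels x samples matrix (for fMRI: time x voxels).
#' @param max_order largest candidate order (capped at min(dim) - 1).
#' @return an \code{order_estimate}: list with \code{method = "laplace"},
#'   \code{candidates}, \code{scores} (log-evidence) and \code{chosen}.
#' @export
estimate_order_laplace <- function(data, max_order = NULL) {
  data <- as.matrix(data)
  # variables = rows (channels); samples = columns. Work on whichever
  # covariance is smaller; the nonzero eigenvalues agree.
  d <- nrow(data); N <- ncol(data)
  assert_that(N > 1 && d > 1, "need at least a 2x2 matrix")
  if (d > N) { data <- t(data); d <- nrow(data); N <- ncol(data) }
  xc <- data - rowMeans(data)
  lambda <- eigen(tcrossprod(xc) / N, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, .Machine$double.eps)
  max_order <- min(max_order %||% (d - 1L), d - 1L)
  candidates <- seq_len(max_order)
  scores <- vapply(candidates, function(k)
    minka_log_evidence(lambda, k, N, d), numeric(1))
  structure(list(method = "laplace", candidates = candidates, scores = scores,
                 chosen = candidates[which.max(scores)]),
            class = "order_estimate")
}

# Minka's Laplace-approximation log-evidence for PCA dimensionality k,
# given the d sample-covariance eigenvalues (descending) and N samples.
minka_log_evidence <- function(lambda, k, N, d) {
  v <- mean(lambda[(k + 1):d])
  if (v <= 0) return(-Inf)
  i <- seq_len(k)
  log_pU <- -k * log(2) + sum(lgamma((d - i + 1) / 2) -
                              ((d - i + 1) / 2) * log(pi))
  m <- d * k - k * (k + 1) / 2
  lam_hat <- c(lambda[seq_len(k)], rep(v, d - k))
  log_Az <- 0
  for (ii in seq_len(k)) {
    jj <- (ii + 1):d
    terms <- (1 / lam_hat[jj] - 1 / lam_hat[ii]) * (lambda[ii] - lambda[jj]) * N
    log_Az <- log_Az + sum(log(pmax(terms, .Machine$double.eps)))
  }
  log_pU - (N / 2) * sum(log(lambda[seq_len(k)])) -
    (N * (d - k) / 2) * log(v) + ((m + k) / 2) * log(2 * pi) -
    log_Az / 2 - (k / 2) * log(N)
}

#' Mean order across subjects (round-half-up)
#'
#' @param subject_orders non-empty integer vector of per-subject orders.
#' @return rounded arithmetic mean.
#' @export
mean_order <- function(subject_orders) {
  assert_that(length(subject_orders) > 0, "subject_orders must be non-empty")
  as.integer(round_half_up(mean(subject_orders)))
}

#' ICASSO stability-based order selection
#'
#' For each candidate order, runs \code{n_runs} randomised fastica
#' decompositions, pools all components, clusters them by 1 - |correlation|
#' dissimilarity (average-linkage agglomeration cut at the candidate order)
#' and scores each cluster with the stability index
#' Iq = mean within-cluster similarity - mean between-cluster similarity.
#' The chosen order maximises the mean Iq, with smaller sd then smaller IQR
#' as tie-breakers.
#'
#' @param data channels x samples matrix.
#' @param order_min,order_max candidate order range.
#' @param n_runs randomized restarts per candidate (>= 2).
#' @param seed integer seed.
#' @param ... passed to \code{\link{fastica}}.
#' @return an \code{order_estimate} with per-candidate \code{scores} data frame
#'   (mean, median, sd, iqr of Iq) and \code{chosen}.
#' @export
icasso_select <- function(data, order_min, order_max, n_runs = 20L, seed = 1L,
                          ...) {
  assert_that(order_min <= order_max, "order_min must be <= order_max")
  assert_that(n_runs >= 2, "need at least 2 runs")
  candidates <- seq.int(order_min, order_max)
  seeds <- derive_seeds(seed, length(candidates) * n_runs)
  stats_list <- lapply(seq_along(candidates), function(ci) {
    q <- candidates[ci]
    runs <- lapply(seq_len(n_runs), function(r) {
      m <- withCallingHandlers(
        fastica(data, q, seed = seeds[(ci - 1L) * n_runs + r], ...),
        warning = function(w) invokeRestart("muffleWarning"))
      if (m$converged) m$S else NULL
    })
    bad <- vapply(runs, is.null, logical(1))
    if (any(bad))
      warning(sum(bad), " non-convergent run(s) excluded at order ", q)
    runs <- runs[!bad]
    if (length(runs) < 2) return(c(mean = NA, median = NA, sd = NA, iqr = NA))
    pooled <- do.call(rbind, runs)
    iq <- cluster_stability(pooled, q)
    c(mean = mean(iq), median = median(iq), sd = sd(iq), iqr = IQR(iq))
  })
  scores <- as.data.frame(do.call(rbind, stats_list))
  scores$order <- candidates
  # max mean Iq; ties broken by smaller sd, then smaller IQR
  ord <- order(-scores$mean, scores$sd, scores$iqr)
  chosen <- candidates[ord[1]]
  structure(list(method = "icasso", candidates = candidates, scores = scores,
                 chosen = chosen),
            class = "order_estimate")
}

# Cluster pooled components (rows) into k clusters by 1-|cor| and return the
# per-cluster stability index Iq.
cluster_stability <- function(pooled, k) {
  simil <- abs(cor(t(pooled)))
  diss <- as.dist(1 - simil)
  cl <- cutree(hclust(diss, method = "average"), k = k)
  vapply(seq_len(k), function(j) {
    inside <- which(cl == j)
    outside <- which(cl != j)
    within <- if (length(inside) > 1) {
      sub <- simil[inside, inside]
      mean(sub[upper.tri(sub)])
    } else 1
    between <- if (length(outside) > 0)
      mean(simil[inside, outside, drop = FALSE]) else 0
    within - between
  }, numeric(1))
}

#' @export
print.order_estimate <- function(x, ...) {
  cat(sprintf("<order_estimate (%s): chosen %d of candidates %d..%d>\n",
              x$method, x$chosen, min(x$candidates), max(x$candidates)))
  invisible(x)
}
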