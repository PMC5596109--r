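#' Closeness between a component map and a spatial reference
#'
#' Defined as minus the absolute Pearson correlation, so smaller means closer
#' and the measure is invariant to the sign and scale of either map. Bounded
#' in [-1, 0].
#'
#' @param y,r numeric vectors of equal length, both non-constant.
#' @return scalar closeness value.
#' @export
closeness <- function(y, r) {
  assert_that(length(y) == length(r), "maps must have equal length")
  if (pop_sd(y) == 0 || pop_sd(r) == 0)
    stop("closeness undefined for a constant map")
  -abs(cor(y, r))
}

#' Build spatial references from feature maps
#'
#' Each map is z-scored over in-mask voxels (population sd) and voxels with
#' z below \code{z_ref} are set to zero — a slight thresholding that keeps the
#' activated part of the map as the reference signal.
#'
#' @param maps k x V matrix or \code{feature_map_set}.
#' @param z_ref z threshold (default 1.0).
#' @param source_level provenance tag ("intergroup", "intragroup" or
#'   "intragroup_specific").
#' @return a \code{reference_set}: list with \code{references} (k x V),
#'   \code{z_ref}, \code{source_level}.
#' @export
make_references <- function(maps, z_ref = 1.0, source_level = "intragroup") {
  if (inherits(maps, "feature_map_set")) {
    source_level <- maps$level
    maps <- maps$maps
  }
  z <- zscore_rows(maps)
  z[z < z_ref] <- 0
  nz <- rowSums(z != 0)
  if (any(nz == 0))
    stop("reference map(s) ", paste(which(nz == 0), collapse = ", "),
         " have no voxel at or above z_ref = ", z_ref)
  structure(list(references = z, z_ref = z_ref, source_level = source_level),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set: %d references x %d voxels, z_ref=%g, from %s>\n",
              nrow(x$references), ncol(x$references), x$z_ref, x$source_level))
  invisible(x)
}

#' Constrained ICA with spatial references (ICA-R / GIG-ICA style)
#'
#' For each reference independently, extracts from the mixture the single
#' unit-variance component that maximises the negentropy contrast J(y)
#' subject to the closeness constraint \code{closeness(y, r) <= xi} and
#' E(y^2) = 1. The unmixing vector is initialised from the reference's
#' projection onto the whitened mixture space and refined with a one-unit
#' fixed-point (Newton-like) step combined with an augmented-Lagrangian
#' multiplier on the closeness constraint.
#'
#' The closeness bound xi defaults to \code{"auto"}: each reference gets its
#' own bound, the closeness achieved by the initial projection loosened by
#' \code{xi_slack} (never tighter than the floor of -0.5). This keeps the
#' extraction in a cone around the best reference-matching combination while
#' negentropy is maximised within it — the behaviour that lets group
#' references denoise individual components. A numeric \code{xi} is applied
#' to all references as given.
#'
#' @param mixture n_maps x V matrix (feature maps in rows) or
#'   \code{feature_map_set}.
#' @param refs a \code{\link{make_references}} result, or a plain k x V matrix
#'   (thresholded references used as-is).
#' @param xi \code{"auto"} (default, adaptive per-reference bound) or a
#'   numeric closeness bound in [-1, 0]; e.g. -0.5 requires
#'   |corr(y, r)| >= 0.5.
#' @param xi_slack closeness headroom above the initial projection used by
#'   the adaptive bound.
#' @param seed integer seed (used only for a degenerate random fallback
#'   initialisation).
#' @param max_iter,tol iteration controls.
#' @param nonlinearity contrast nonlinearity, as in \code{\link{fastica}}.
#' @return a \code{feature_map_set} with one component per reference (level
#'   "constrained" unless relabelled by the caller) carrying per-component
#'   \code{converged} and \code{constraint_violated} flags.
#' @export
icar_extract <- function(mixture, refs, xi = "auto", xi_slack = 0.02,
                         seed = 1L, max_iter = 500L, tol = 1e-6,
                         nonlinearity = "tanh") {
  set_meta <- NULL
  if (inherits(mixture, "feature_map_set")) {
    set_meta <- mixture
    mixture <- mixture$maps
  }
  R <- if (inherits(refs, "reference_set")) refs$references else as.matrix(refs)
  n_refs <- nrow(R)
  assert_that(ncol(R) == ncol(mixture), "mixture/reference voxel mismatch")
  assert_that(nrow(mixture) >= n_refs,
              "mixture must have at least as many maps as references")
  nl <- ica_nonlinearity(nonlinearity)
  wh <- center_whiten(mixture, nrow(mixture))
  Z <- wh$z
  V <- ncol(Z)
  q <- nrow(Z)
  seeds <- derive_seeds(seed, n_refs)

  adaptive <- identical(xi, "auto")
  if (!adaptive)
    assert_that(is.numeric(xi) && xi <= 0 && xi >= -1,
                "numeric xi must lie in [-1, 0]")

  out <- matrix(0, n_refs, V)
  converged <- logical(n_refs)
  violated <- logical(n_refs)
  xi_used <- numeric(n_refs)
  for (j in seq_len(n_refs)) {
    r <- R[j, ]
    rstd <- (r - mean(r)) / pop_sd(r)
    cvec <- Z %*% rstd / V            # corr(w'Z, r) = w'cvec for unit w
    cn <- sqrt(sum(cvec^2))
    w <- if (cn > 1e-12) as.vector(cvec) / cn
         else with_seed(seeds[j], { v <- rnorm(q); v / sqrt(sum(v^2)) })
    # bound: adaptively tightened to the initial projection's closeness
    xi_j <- if (adaptive) min(-cn + xi_slack, -0.5) else xi
    xi_used[j] <- xi_j
    mu <- 0                            # augmented-Lagrangian multiplier
    rho_pen <- 1
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      y <- drop(crossprod(w, Z))
      # one-unit fixed-point (Newton-like) step on negentropy
      w_ica <- Z %*% nl$g(y) / V - mean(nl$dg(y)) * w
      # constraint g = -|w'c| - xi <= 0; ascend |corr| while active
      corr_j <- sum(w * cvec)
      gval <- -abs(corr_j) - xi_j
      mu <- max(0, mu + rho_pen * gval)
      w_new <- as.vector(w_ica) + mu * sign(corr_j) * as.vector(cvec)
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) break
      w_new <- w_new / nrm
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- w_new
      if (delta < tol) { ok <- TRUE; break }
    }
    corr_j <- sum(w * cvec)
    if (corr_j < 0) { w <- -w; corr_j <- -corr_j }  # align with reference
    # restore feasibility exactly when the boundary equilibrium drifted out
    # (possible only when the target correlation -xi_j is achievable, i.e.
    # -xi_j <= cn, the projection's correlation)
    if (-corr_j - xi_j > 1e-9 && -xi_j <= cn && cn > 1e-12) {
      chat <- as.vector(cvec) / cn
      alpha <- (-xi_j) / cn
      u <- w - sum(w * chat) * chat
      un <- sqrt(sum(u^2))
      w <- if (un > 1e-12) alpha * chat + sqrt(max(0, 1 - alpha^2)) * u / un
           else chat
      corr_j <- sum(w * cvec)
    }
    y <- drop(crossprod(w, Z))
    out[j, ] <- y
    converged[j] <- ok
    violated[j] <- (-corr_j - xi_j) > 1e-6
  }
  feature_map_set(out, level = "constrained",
                  dataset_id = set_meta$dataset_id,
                  subject_id = set_meta$subject_id,
                  mask = set_meta$mask, shape = set_meta$shape,
                  seed = seed,
                  provenance = list(method = "icar", xi = xi,
                                    xi_used = xi_used, n_refs = n_refs),
                  converged = converged, constraint_violated = violated)
}
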