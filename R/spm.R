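#' z-score a spatial map into a statistical parametric map
#'
#' Standardises the map over in-mask voxels with the population (1/N) sd, so
#' the result has mean 0 and sd 1 exactly. Affine transforms of the input
#' (positive scale) leave the result unchanged.
#'
#' @param map numeric vector of voxel values.
#' @param mask optional logical vector; out-of-mask voxels are left at 0.
#' @param shape optional spatial dims, carried to downstream thresholding.
#' @return an \code{spm_map}: list with \code{z_values}, \code{mask},
#'   \code{shape}.
#' @export
zscore_map <- function(map, mask = NULL, shape = NULL) {
  map <- as.numeric(map)
  mask <- mask %||% rep(TRUE, length(map))
  x <- map[mask]
  s <- pop_sd(x)
  if (s == 0) stop("cannot z-score a constant map")
  z <- numeric(length(map))
  z[mask] <- (x - mean(x)) / s
  structure(list(z_values = z, mask = mask, shape = shape), class = "spm_map")
}

# Label connected components of a logical voxel vector on a 2D/3D grid.
# connectivity: 8 in 2D, 26 in 3D (all diagonal neighbours).
label_clusters <- function(keep, shape) {
  labels <- integer(length(keep))
  idx <- which(keep)
  if (length(idx) == 0) return(labels)
  ndim <- length(shape)
  pos <- arrayInd(idx, .dim = shape)
  lut <- integer(prod(shape))
  lut[idx] <- seq_along(idx)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), ndim)))
  # keep one of each +/- pair to avoid duplicate edges
  offsets <- offsets[apply(offsets, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0
  }), , drop = FALSE]
  strides <- cumprod(c(1, shape[-ndim]))
  edges <- NULL
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    np <- sweep(pos, 2L, off, "+")
    ok <- rep(TRUE, nrow(np))
    for (dmn in seq_len(ndim))
      ok <- ok & np[, dmn] >= 1 & np[, dmn] <= shape[dmn]
    if (!any(ok)) next
    nlin <- as.integer((np[ok, , drop = FALSE] - 1) %*% strides) + 1L
    j <- lut[nlin]
    hit <- j > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], j[hit]))
  }
  if (is.null(edges)) {
    labels[idx] <- seq_along(idx)
    return(labels)
  }
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  labels[idx] <- igraph::components(g)$membership
  labels
}

#' Threshold an SPM and remove small clusters
#'
#' Voxels with z at or above \code{z_threshold} (one-sided, positive tail) are
#' labeled into connected components (8-connectivity in 2D, 26 in 3D);
#' clusters smaller than \code{min_cluster} voxels are zeroed. The defaults
#' z = 2.0 and 10 voxels are the standard settings for delivering the final
#' brain functional networks.
#'
#' @param spm an \code{spm_map} (or plain numeric vector, with \code{shape}).
#' @param z_threshold z cutoff (default 2.0).
#' @param min_cluster minimum surviving cluster size in voxels (default 10).
#' @param shape spatial dims (required if not carried by \code{spm}).
#' @return a \code{bfn_map}: list with thresholded \code{z_values},
#'   \code{z_threshold}, \code{min_cluster_size}, \code{labels} (cluster label
#'   per voxel), \code{cluster_sizes}, \code{n_voxels} surviving, \code{empty}
#'   flag, \code{shape}.
#' @export
threshold_clusters <- function(spm, z_threshold = 2.0, min_cluster = 10L,
                               shape = NULL) {
  assert_that(min_cluster >= 1, "min_cluster must be >= 1")
  assert_that(is.finite(z_threshold), "z_threshold must be finite")
  if (inherits(spm, "spm_map")) {
    z <- spm$z_values
    shape <- shape %||% spm$shape
  } else z <- as.numeric(spm)
  if (is.null(shape)) stop("spatial shape required for cluster labeling")
  assert_that(prod(shape) == length(z), "shape does not match map length")
  keep <- z >= z_threshold
  labels <- label_clusters(keep, shape)
  sizes <- tabulate(labels)
  small <- which(sizes < min_cluster)
  if (length(small)) {
    drop_vox <- labels %in% small
    keep[drop_vox] <- FALSE
    labels[drop_vox] <- 0L
  }
  # relabel surviving clusters 1..K in decreasing size order
  surv <- which(sizes >= min_cluster)
  if (length(surv)) {
    surv <- surv[order(-sizes[surv])]
    relab <- integer(max(labels))
    relab[surv] <- seq_along(surv)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    sizes <- sizes[surv]
  } else sizes <- integer(0)
  zt <- ifelse(keep, z, 0)
  structure(list(z_values = zt, z_threshold = z_threshold,
                 min_cluster_size = as.integer(min_cluster), labels = labels,
                 cluster_sizes = sizes, n_voxels = sum(keep),
                 empty = !any(keep), shape = shape),
            class = "bfn_map")
}

#' @export
print.bfn_map <- function(x, ...) {
  cat(sprintf("<bfn_map: %d voxels in %d cluster(s) at z>=%g, min cluster %d%s>\n",
              x$n_voxels, length(x$cluster_sizes), x$z_threshold,
              x$min_cluster_size, if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Cluster table for a BFN map
#'
#' @param bfn a \code{bfn_map}.
#' @return data frame with label, size, peak z and peak voxel coordinates.
#' @export
bfn_cluster_table <- function(bfn) {
  stopifnot(inherits(bfn, "bfn_map"))
  if (bfn$empty)
    return(data.frame(label = integer(0), size = integer(0),
                      peak_z = numeric(0), peak_voxel = integer(0)))
  labs <- sort(unique(bfn$labels[bfn$labels > 0]))
  rows <- lapply(labs, function(l) {
    vox <- which(bfn$labels == l)
    pk <- vox[which.max(bfn$z_values[vox])]
    data.frame(label = l, size = length(vox),
               peak_z = max(bfn$z_values[vox]), peak_voxel = pk)
  })
  do.call(rbind, rows)
}
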