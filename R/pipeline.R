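#' A set of spatial feature maps at one hierarchy level
#'
#' The single currency passed between levels of the framework: a
#' components x voxels matrix tagged with its level and provenance.
#'
#' @param maps k x V numeric matrix, no all-zero rows.
#' @param level one of "subject", "intragroup", "intergroup",
#'   "intragroup_specific", "subject_specific", "constrained".
#' @param dataset_id,subject_id identifiers; subject-level sets need both,
#'   intergroup sets neither, dataset-level sets need \code{dataset_id}.
#' @param mask,shape spatial metadata (optional).
#' @param seed seed that produced the set.
#' @param provenance free-form list describing the producing run.
#' @param converged,constraint_violated optional per-component flags.
#' @return object of class \code{feature_map_set}.
#' @export
feature_map_set <- function(maps, level, dataset_id = NULL, subject_id = NULL,
                            mask = NULL, shape = NULL, seed = NULL,
                            provenance = NULL, converged = NULL,
                            constraint_violated = NULL) {
  maps <- as.matrix(maps)
  levels_ok <- c("subject", "intragroup", "intergroup", "intragroup_specific",
                 "subject_specific", "constrained")
  assert_that(level %in% levels_ok,
              paste("level must be one of:", paste(levels_ok, collapse = ", ")))
  assert_that(!any(apply(maps, 1L, function(r) all(r == 0))),
              "feature map set contains an all-zero map")
  if (level == "subject" || level == "subject_specific")
    assert_that(!is.null(dataset_id) && !is.null(subject_id),
                paste(level, "level sets need dataset_id and subject_id"))
  if (level %in% c("intragroup", "intragroup_specific"))
    assert_that(!is.null(dataset_id), paste(level, "level sets need dataset_id"))
  structure(list(maps = maps, level = level, dataset_id = dataset_id,
                 subject_id = subject_id, mask = mask, shape = shape,
                 order = nrow(maps), seed = seed, provenance = provenance,
                 converged = converged,
                 constraint_violated = constraint_violated),
            class = "feature_map_set")
}

#' @export
print.feature_map_set <- function(x, ...) {
  ids <- paste(c(x$dataset_id, x$subject_id), collapse = "/")
  cat(sprintf("<feature_map_set [%s%s]: %d maps x %d voxels>\n", x$level,
              if (nzchar(ids)) paste0(" ", ids) else "", nrow(x$maps),
              ncol(x$maps)))
  invisible(x)
}

#' First-level (single-subject) spatial ICA
#'
#' Decomposes each subject's time x voxel data with fixed-point ICA; the
#' spatial maps become that subject's feature maps. The per-subject order
#' comes from the Laplace-approximation estimator unless fixed.
#'
#' @param subjects list of \code{\link{subject_data}}.
#' @param order "laplace" (default) or a fixed integer order.
#' @param max_order cap for the Laplace candidate range.
#' @param seed integer master seed; per-subject seeds derive from it.
#' @param ... passed to \code{\link{fastica}}.
#' @return list of subject-level \code{feature_map_set}s (one per subject;
#'   failed subjects yield NULL with the error recorded in the
#'   \code{"errors"} attribute).
#' @export
first_level <- function(subjects, order = "laplace", max_order = NULL,
                        seed = 1L, ...) {
  seeds <- derive_seeds(seed, length(subjects))
  errors <- list()
  sets <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    sets[[i]] <- tryCatch({
      X <- sub$data  # time x voxel: channels in rows, voxels as samples
      k <- if (identical(order, "laplace"))
        estimate_order_laplace(X, max_order)$chosen else as.integer(order)
      model <- fastica(X, k, seed = seeds[i], ...)
      feature_map_set(model$S, level = "subject", dataset_id = sub$dataset_id,
                      subject_id = sub$subject_id, mask = sub$mask,
                      shape = sub$shape, seed = seeds[i],
                      provenance = list(stage = "first_level", order = k,
                                        converged = model$converged,
                                        n_iterations = model$n_iterations))
    }, error = function(e) {
      errors[[sub$subject_id]] <<- conditionMessage(e)
      NULL
    })
  }
  attr(sets, "errors") <- errors
  sets
}

#' Row-concatenate feature-map sets with provenance
#'
#' @param sets list of \code{feature_map_set}s sharing voxel dimension and
#'   mask.
#' @return list with \code{maps} (sum(k_i) x V matrix) and \code{provenance}
#'   (data frame mapping each row to its set, dataset, subject and component).
#' @export
aggregate_maps <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  assert_that(length(sets) > 0, "no feature map sets to aggregate")
  V <- ncol(sets[[1]]$maps)
  for (s in sets) {
    assert_that(ncol(s$maps) == V, "voxel dimension mismatch across sets")
    if (!is.null(s$mask) && !is.null(sets[[1]]$mask))
      assert_that(identical(s$mask, sets[[1]]$mask), "mask mismatch across sets")
  }
  maps <- do.call(rbind, lapply(sets, `[[`, "maps"))
  prov <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(set = i,
               dataset_id = s$dataset_id %||% NA_character_,
               subject_id = s$subject_id %||% NA_character_,
               component = seq_len(nrow(s$maps)))
  }))
  list(maps = maps, provenance = prov, mask = sets[[1]]$mask,
       shape = sets[[1]]$shape)
}

#' Second-level (intragroup) ICA on aggregated feature maps
#'
#' Runs ICA on the stacked subject feature maps of one dataset, treating maps
#' as observation rows over voxel samples (feature-based group ICA). The rows
#' are PCA-reduced to the target order before the fixed-point iteration. The
#' order defaults to the rounded mean of the per-subject orders.
#'
#' @param aggregated result of \code{\link{aggregate_maps}} (or a plain
#'   matrix).
#' @param subject_orders per-subject orders feeding \code{\link{mean_order}}.
#' @param order fixed order override.
#' @param dataset_id identifier for the output set.
#' @param seed integer seed.
#' @param ... passed to \code{\link{fastica}}.
#' @return intragroup-level \code{feature_map_set}.
#' @export
second_level <- function(aggregated, subject_orders = NULL, order = NULL,
                         dataset_id = "ds1", seed = 1L, ...) {
  maps <- if (is.list(aggregated) && !is.null(aggregated$maps))
    aggregated$maps else as.matrix(aggregated)
  k <- order %||% mean_order(subject_orders)
  assert_that(nrow(maps) >= k, "fewer aggregated maps than the target order")
  model <- fastica(maps, k, seed = seed, ...)
  feature_map_set(model$S, level = "intragroup", dataset_id = dataset_id,
                  mask = if (is.list(aggregated)) aggregated$mask else NULL,
                  shape = if (is.list(aggregated)) aggregated$shape else NULL,
                  seed = seed,
                  provenance = list(stage = "second_level", order = k,
                                    converged = model$converged,
                                    n_iterations = model$n_iterations))
}

#' Third-level (intergroup) ICA across datasets
#'
#' Aggregates the intragroup feature maps of m >= 2 datasets and decomposes
#' them once more. The order is the rounded average of the per-dataset
#' component counts when the datasets are repeated sessions of the same
#' subjects; otherwise ICASSO stability selection runs over the range
#' [min, max] of those counts.
#'
#' @param intragroup_sets list of intragroup \code{feature_map_set}s (m >= 2).
#' @param same_subjects TRUE when the datasets are sessions of the same
#'   subjects.
#' @param seed integer seed.
#' @param n_runs ICASSO restarts per candidate order.
#' @param ... passed to \code{\link{fastica}}.
#' @return intergroup-level \code{feature_map_set}; the ICASSO
#'   \code{order_estimate} (when used) is stored in the provenance.
#' @export
third_level <- function(intragroup_sets, same_subjects = TRUE, seed = 1L,
                        n_runs = 10L, ...) {
  if (length(intragroup_sets) < 2)
    stop("third-level ICA needs m >= 2 datasets; with m = 1 the hierarchy ",
         "stops at the intragroup level (use its maps as references)")
  counts <- vapply(intragroup_sets, function(s) nrow(s$maps), integer(1))
  agg <- aggregate_maps(intragroup_sets)
  est <- NULL
  k <- if (same_subjects) {
    as.integer(round_half_up(mean(counts)))
  } else {
    est <- icasso_select(agg$maps, min(counts), max(counts), n_runs = n_runs,
                         seed = seed, ...)
    est$chosen
  }
  model <- fastica(agg$maps, k, seed = seed, ...)
  feature_map_set(model$S, level = "intergroup", mask = agg$mask,
                  shape = agg$shape, seed = seed,
                  provenance = list(stage = "third_level", order = k,
                                    same_subjects = same_subjects,
                                    order_estimate = est,
                                    converged = model$converged))
}

#' Re-estimate level-specific maps by constrained ICA
#'
#' Thresholds the reference maps at \code{z_ref}, then runs
#' \code{\link{icar_extract}} on every target set. Output component j always
#' corresponds to reference j, so specific maps inherit the reference order.
#'
#' @param target_sets a \code{feature_map_set} or list of them (subject sets
#'   give subject-specific output; intragroup sets give intragroup-specific
#'   output).
#' @param reference_maps \code{feature_map_set} or k x V matrix providing the
#'   references.
#' @param z_ref reference z threshold (default 1.0).
#' @param xi closeness bound passed to \code{\link{icar_extract}}.
#' @param seed integer seed.
#' @param ... passed to \code{\link{icar_extract}}.
#' @return list of \code{feature_map_set}s (level relabelled to
#'   "*_specific"); failed targets yield NULL with errors in the
#'   \code{"errors"} attribute.
#' @export
reestimate_specific <- function(target_sets, reference_maps, z_ref = 1.0,
                                xi = "auto", seed = 1L, ...) {
  single <- inherits(target_sets, "feature_map_set")
  if (single) target_sets <- list(target_sets)
  refs <- make_references(reference_maps, z_ref = z_ref)
  seeds <- derive_seeds(seed, length(target_sets))
  errors <- list()
  out <- vector("list", length(target_sets))
  for (i in seq_along(target_sets)) {
    tgt <- target_sets[[i]]
    out[[i]] <- tryCatch({
      res <- icar_extract(tgt, refs, xi = xi, seed = seeds[i], ...)
      res$level <- switch(tgt$level,
                          subject = "subject_specific",
                          intragroup = "intragroup_specific",
                          "constrained")
      res
    }, error = function(e) {
      key <- paste(tgt$dataset_id %||% "?", tgt$subject_id %||% "?", sep = "/")
      errors[[key]] <<- conditionMessage(e)
      NULL
    })
  }
  attr(out, "errors") <- errors
  if (single) out[[1]] else out
}

#' Configuration for a full hierarchical run
#'
#' @param first_order "laplace" or a fixed integer per-subject order.
#' @param second_order fixed intragroup order; default NULL uses the rounded
#'   mean of the subject orders.
#' @param z_ref reference z threshold for constrained re-estimation.
#' @param xi closeness bound for constrained re-estimation.
#' @param z_threshold,min_cluster BFN thresholding parameters.
#' @param subject_reference "auto" (intragroup-specific maps when m >= 2, the
#'   single intragroup set when m = 1), "intergroup", or
#'   "intragroup_specific".
#' @param same_subjects are the datasets repeated sessions of one subject
#'   group (drives the third-level order rule)?
#' @param max_order cap for Laplace order estimation.
#' @param n_runs_icasso ICASSO restarts per candidate.
#' @param make_bfns also deliver thresholded BFN maps for every output set.
#' @param seed master integer seed.
#' @return a list of class \code{fmica_config}.
#' @export
fmica_config <- function(first_order = "laplace", second_order = NULL,
                         z_ref = 1.0, xi = "auto", z_threshold = 2.0,
                         min_cluster = 10L,
                         subject_reference = c("auto", "intergroup",
                                               "intragroup_specific"),
                         same_subjects = TRUE, max_order = NULL,
                         n_runs_icasso = 10L, make_bfns = TRUE, seed = 1L) {
  structure(list(first_order = first_order, second_order = second_order,
                 z_ref = z_ref, xi = xi, z_threshold = z_threshold,
                 min_cluster = as.integer(min_cluster),
                 subject_reference = match.arg(subject_reference),
                 same_subjects = same_subjects, max_order = max_order,
                 n_runs_icasso = n_runs_icasso, make_bfns = make_bfns,
                 seed = as.integer(seed)),
            class = "fmica_config")
}

bfns_for_set <- function(set, config) {
  if (is.null(set)) return(NULL)
  shape <- set$shape %||% stop("feature map set lacks spatial shape for BFNs")
  lapply(seq_len(nrow(set$maps)), function(k) {
    spm <- zscore_map(set$maps[k, ], shape = shape)
    threshold_clusters(spm, z_threshold = config$z_threshold,
                       min_cluster = config$min_cluster)
  })
}

#' Run the full feature-map ICA hierarchy
#'
#' Executes first-level per-subject ICA, second-level intragroup ICA per
#' dataset, third-level intergroup ICA (when m >= 2), constrained
#' re-estimation of intragroup-specific maps (m >= 2) and of subject-specific
#' maps, and converts delivered sets into thresholded BFN maps. With a single
#' dataset (m = 1), no intergroup or intragroup-specific maps are produced and
#' the intragroup maps serve as the subject-specific references.
#'
#' @param datasets named list: dataset id -> list of
#'   \code{\link{subject_data}}.
#' @param config a \code{\link{fmica_config}}.
#' @return an \code{fmica_result}: list with \code{subject_sets} (per dataset),
#'   \code{intragroup_sets}, \code{intergroup_set} (NULL when m = 1),
#'   \code{intragroup_specific_sets} (NULL when m = 1),
#'   \code{subject_specific_sets}, \code{bfns} (per delivered level),
#'   \code{orders} log, \code{errors}, \code{config}.
#' @export
run_fmica <- function(datasets, config = fmica_config()) {
  assert_that(length(datasets) >= 1, "need at least one dataset")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- sprintf("ds%d", seq_along(datasets))
  m <- length(datasets)
  stage_seeds <- derive_seeds(config$seed, 4L)
  errors <- list()
  orders <- list()

  # Level 1: per-subject ICA, per dataset
  ds_seeds <- derive_seeds(stage_seeds[1], m)
  subject_sets <- lapply(seq_len(m), function(k) {
    sets <- first_level(datasets[[k]], order = config$first_order,
                        max_order = config$max_order, seed = ds_seeds[k])
    errs <- attr(sets, "errors")
    if (length(errs)) errors[[names(datasets)[k]]] <<- errs
    sets
  })
  names(subject_sets) <- names(datasets)
  orders$first <- lapply(subject_sets, function(sets)
    vapply(Filter(Negate(is.null), sets), function(s) s$order, integer(1)))

  # Level 2: intragroup ICA per dataset
  ds_seeds2 <- derive_seeds(stage_seeds[2], m)
  intragroup_sets <- lapply(seq_len(m), function(k) {
    ok_sets <- Filter(Negate(is.null), subject_sets[[k]])
    agg <- aggregate_maps(ok_sets)
    second_level(agg, subject_orders = orders$first[[k]],
                 order = config$second_order,
                 dataset_id = names(datasets)[k], seed = ds_seeds2[k])
  })
  names(intragroup_sets) <- names(datasets)
  orders$second <- vapply(intragroup_sets, `[[`, integer(1), "order")

  # Level 3 + intragroup-specific re-estimation (only when m >= 2)
  intergroup_set <- NULL
  intragroup_specific_sets <- NULL
  if (m >= 2) {
    intergroup_set <- third_level(intragroup_sets,
                                  same_subjects = config$same_subjects,
                                  seed = stage_seeds[3],
                                  n_runs = config$n_runs_icasso)
    orders$third <- intergroup_set$order
    intragroup_specific_sets <- reestimate_specific(
      intragroup_sets, intergroup_set, z_ref = config$z_ref, xi = config$xi,
      seed = stage_seeds[3])
    names(intragroup_specific_sets) <- names(datasets)
  }

  # Subject-specific re-estimation
  sub_seeds <- derive_seeds(stage_seeds[4], m)
  subject_specific_sets <- lapply(seq_len(m), function(k) {
    refs <- if (m == 1) {
      intragroup_sets[[1]]
    } else if (config$subject_reference == "intergroup") {
      intergroup_set
    } else {
      intragroup_specific_sets[[k]] %||% intergroup_set
    }
    res <- reestimate_specific(Filter(Negate(is.null), subject_sets[[k]]),
                               refs, z_ref = config$z_ref, xi = config$xi,
                               seed = sub_seeds[k])
    errs <- attr(res, "errors")
    if (length(errs))
      errors[[paste0(names(datasets)[k], ":specific")]] <<- errs
    res
  })
  names(subject_specific_sets) <- names(datasets)

  bfns <- NULL
  if (isTRUE(config$make_bfns)) {
    bfns <- list(
      intragroup = lapply(intragroup_sets, bfns_for_set, config = config),
      intergroup = if (!is.null(intergroup_set))
        bfns_for_set(intergroup_set, config),
      intragroup_specific = if (!is.null(intragroup_specific_sets))
        lapply(intragroup_specific_sets, bfns_for_set, config = config),
      subject_specific = lapply(subject_specific_sets, function(sets)
        lapply(Filter(Negate(is.null), sets), bfns_for_set, config = config))
    )
  }

  structure(list(subject_sets = subject_sets,
                 intragroup_sets = intragroup_sets,
                 intergroup_set = intergroup_set,
                 intragroup_specific_sets = intragroup_specific_sets,
                 subject_specific_sets = subject_specific_sets,
                 bfns = bfns, orders = orders, errors = errors,
                 config = config),
            class = "fmica_result")
}

#' @export
print.fmica_result <- function(x, ...) {
  m <- length(x$subject_sets)
  cat(sprintf("<fmica_result: %d dataset(s)%s>\n", m,
              if (is.null(x$intergroup_set)) " (no intergroup level, m = 1)"
              else sprintf(", intergroup order %d", x$intergroup_set$order)))
  for (k in seq_len(m))
    cat(sprintf("  %s: %d subjects, intragroup order %d\n",
                names(x$subject_sets)[k],
                length(x$subject_sets[[k]]), x$orders$second[k]))
  invisible(x)
}
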