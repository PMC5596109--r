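#' One subject's fMRI data as a time x voxel matrix
#'
#' @param data numeric \code{time x voxel} matrix (voxels restricted to the
#'   mask).
#' @param tr repetition time in seconds (> 0).
#' @param shape spatial dimensions of the original volume (2 or 3 integers).
#' @param mask logical vector over the full volume (\code{prod(shape)} long);
#'   \code{sum(mask)} must equal \code{ncol(data)}. Default: all voxels.
#' @param subject_id,dataset_id identifiers.
#' @param affine optional 4x4 affine carried through to output NIfTI files.
#' @return object of class \code{subject_data}.
#' @export
subject_data <- function(data, tr, shape, mask = NULL,
                         subject_id = "sub01", dataset_id = "ds1",
                         affine = NULL) {
  data <- as.matrix(data)
  assert_that(nrow(data) >= 2, "need at least 2 time points")
  assert_that(all(is.finite(data)), "data must be finite")
  assert_that(tr > 0, "TR must be positive")
  mask <- mask %||% rep(TRUE, prod(shape))
  assert_that(sum(mask) == ncol(data),
              "mask true-count must equal the voxel count of data")
  structure(list(data = data, tr = tr, shape = as.integer(shape), mask = mask,
                 subject_id = subject_id, dataset_id = dataset_id,
                 affine = affine),
            class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject_data %s/%s: %d time points x %d voxels, TR=%gs, grid %s>\n",
              x$dataset_id, x$subject_id, nrow(x$data), ncol(x$data), x$tr,
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Load a 4D NIfTI volume as subject data
#'
#' Flattens the volume to a time x voxel matrix under the mask. The default
#' mask keeps voxels with nonzero temporal variance.
#'
#' @param nifti_path path to a 4D NIfTI file.
#' @param mask_path optional NIfTI mask (nonzero = keep); spatial dims must
#'   match.
#' @param tr override TR (defaults to the NIfTI header pixdim).
#' @param subject_id,dataset_id identifiers.
#' @return a \code{\link{subject_data}}.
#' @export
load_subject <- function(nifti_path, mask_path = NULL, tr = NULL,
                         subject_id = basename(nifti_path), dataset_id = "ds1") {
  vol <- RNifti::readNifti(nifti_path)
  d <- dim(vol)
  if (length(d) != 4) stop("expected a 4D volume, got ", length(d), "D: ", nifti_path)
  shape <- d[1:3]
  nt <- d[4]
  arr <- array(vol, dim = c(prod(shape), nt))  # voxel x time
  if (anyNA(arr)) {
    all_na <- apply(arr, 1L, function(v) all(is.na(v)))
    if (all(all_na)) stop("volume contains only NaN voxels: ", nifti_path)
    arr[is.na(arr)] <- 0
  }
  if (!is.null(mask_path)) {
    mvol <- RNifti::readNifti(mask_path)
    if (!identical(as.integer(dim(mvol)[1:3]), as.integer(shape)))
      stop("mask/volume shape mismatch: ", paste(dim(mvol), collapse = "x"),
           " vs ", paste(shape, collapse = "x"))
    mask <- as.vector(mvol != 0)
  } else {
    mask <- apply(arr, 1L, function(v) sd(v) > 0)
  }
  tr <- tr %||% tryCatch(RNifti::pixdim(vol)[4], error = function(e) 1)
  if (!isTRUE(tr > 0)) tr <- 1
  subject_data(t(arr[mask, , drop = FALSE]), tr = tr, shape = shape, mask = mask,
               subject_id = subject_id, dataset_id = dataset_id,
               affine = tryCatch(RNifti::xform(vol), error = function(e) NULL))
}

#' Write a subject's data as 4D NIfTI
#'
#' Inverse of \code{\link{load_subject}}: voxels outside the mask are zero.
#' 2D grids are written as X x Y x 1 x T volumes.
#'
#' @param subject a \code{\link{subject_data}}.
#' @param path output file path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
save_subject <- function(subject, path) {
  shape <- subject$shape
  if (length(shape) == 2) shape <- c(shape, 1L)
  nt <- nrow(subject$data)
  full <- matrix(0, prod(shape), nt)
  full[subject$mask, ] <- t(subject$data)
  arr <- array(full, dim = c(shape, nt))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, subject$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save a feature-map set (or BFN maps) as 4D NIfTI plus JSON sidecar
#'
#' One 4D NIfTI with components along the 4th axis, stored float32, plus a
#' \code{.json} sidecar recording level, ids, order, seed and provenance.
#'
#' @param set a \code{feature_map_set}, or a list of \code{bfn_map}s sharing a
#'   shape.
#' @param out_path output NIfTI path; the sidecar replaces the extension with
#'   \code{.json}.
#' @param shape spatial dims; defaults to the set's recorded shape.
#' @param mask logical volume mask; defaults to the set's mask.
#' @return \code{out_path}, invisibly.
#' @export
save_maps <- function(set, out_path, shape = NULL, mask = NULL) {
  if (inherits(set, "feature_map_set")) {
    maps <- set$maps
    meta <- list(level = set$level, dataset_id = set$dataset_id,
                 subject_id = set$subject_id, order = nrow(maps),
                 seed = set$seed, provenance = set$provenance)
    shape <- shape %||% set$shape
    mask <- mask %||% set$mask
  } else if (is.list(set) && all(vapply(set, inherits, logical(1), "bfn_map"))) {
    maps <- do.call(rbind, lapply(set, function(b) b$z_values))
    meta <- list(level = "bfn", order = length(set),
                 z_threshold = set[[1]]$z_threshold,
                 min_cluster_size = set[[1]]$min_cluster_size)
    shape <- shape %||% set[[1]]$shape
  } else stop("set must be a feature_map_set or a list of bfn_map")
  if (is.null(shape)) stop("spatial shape unknown; pass shape=")
  if (length(shape) == 2) shape <- c(shape, 1L)
  mask <- mask %||% rep(TRUE, prod(shape))
  k <- nrow(maps)
  full <- matrix(0, prod(shape), k)
  full[mask, ] <- t(maps)
  arr <- array(full, dim = c(shape, k))
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, out_path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", out_path)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out_path)
}

#' Reload maps written by \code{\link{save_maps}}
#'
#' @param nifti_path path written by \code{save_maps}.
#' @return list with \code{maps} (k x V over the full volume) and \code{meta}.
#' @export
load_maps <- function(nifti_path) {
  vol <- RNifti::readNifti(nifti_path)
  d <- dim(vol)
  maps <- t(array(vol, dim = c(prod(d[-length(d)]), d[length(d)])))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", nifti_path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  list(maps = maps, meta = meta)
}
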