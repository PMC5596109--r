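#' Simulation configuration for SimTB-style multi-subject fMRI
#'
#' Bundles all generator parameters. The defaults reproduce the study
#' conditions of the simulated experiment: 20 subjects, a 148 x 148 voxel
#' slice, 12 spatial sources, 120 time points at TR = 2 s, baseline intensity
#' 800, contrast-to-noise ratio 1, a 24 s on / 24 s off block design repeated
#' five times, unique events with probability 0.2 per TR, and percent signal
#' change drawn from N(3, 0.25^2). Sources 10 and 12 are task-modulated with
#' task-to-unique amplitude ratios 4 and 2 and unique amplitudes 0.2 and 0.4;
#' all other sources carry unique events of amplitude 1.
#'
#' @param n_subjects number of subjects to simulate.
#' @param grid_side side of the square voxel grid (>= 8).
#' @param n_sources number of spatial sources.
#' @param n_timepoints number of TRs per subject.
#' @param tr repetition time in seconds.
#' @param baseline baseline image intensity.
#' @param cnr contrast-to-noise ratio: sd of the noise-free signal fluctuation
#'   over in-brain voxels divided by the additive Gaussian noise sd.
#' @param task_sources list of lists with fields \code{source} (index),
#'   \code{task_ratio} (task-to-unique amplitude ratio) and \code{unique_amp}.
#' @param unique_event_prob probability of a unique event at each TR.
#' @param psc_mean,psc_sd mean and sd (percent) of the per-timecourse percent
#'   signal change; draws below 0.5 are clipped to 0.5.
#' @param block_on,block_off task block durations in seconds.
#' @param n_blocks number of on/off block cycles.
#' @param variation list with \code{translate_sd} (voxels), \code{rotate_sd}
#'   (degrees) and \code{scale_sd} (ratio): spreads of the zero-mean
#'   per-subject, per-source spatial perturbations.
#' @param seed master integer seed; every random draw in the simulator derives
#'   from it.
#' @param source_maps optional user-supplied n_sources x grid_side^2 matrix of
#'   unit-peak source maps replacing the built-in Gaussian-blob atlas.
#' @param source_centers,source_sigmas optional overrides for the blob atlas:
#'   an n_sources x 2 matrix of centers and an n_sources x 2 matrix of Gaussian
#'   sds (voxels) along the two axes.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 20L,
                       grid_side = 148L,
                       n_sources = 12L,
                       n_timepoints = 120L,
                       tr = 2,
                       baseline = 800,
                       cnr = 1,
                       task_sources = list(
                         list(source = 10L, task_ratio = 4, unique_amp = 0.2),
                         list(source = 12L, task_ratio = 2, unique_amp = 0.4)
                       ),
                       unique_event_prob = 0.2,
                       psc_mean = 3,
                       psc_sd = 0.25,
                       block_on = 24,
                       block_off = 24,
                       n_blocks = 5L,
                       variation = list(translate_sd = 1.5,
                                        rotate_sd = 3,
                                        scale_sd = 0.03),
                       seed = 1L,
                       source_maps = NULL,
                       source_centers = NULL,
                       source_sigmas = NULL) {
  assert_that(grid_side >= 8, "grid_side must be >= 8")
  assert_that(unique_event_prob >= 0 && unique_event_prob <= 1,
              "unique_event_prob must lie in [0, 1]")
  assert_that(cnr > 0, "cnr must be positive")
  assert_that(n_blocks * (block_on + block_off) / tr <= n_timepoints,
              "block design does not fit in n_timepoints")
  if (missing(task_sources))  # default task sources only where they exist
    task_sources <- Filter(function(ts) ts$source <= n_sources, task_sources)
  assert_that(all(vapply(task_sources, function(ts)
    ts$source >= 1 && ts$source <= n_sources, logical(1))),
    "task source index out of range")
  task_sources <- lapply(task_sources, function(ts) {
    ts$source <- as.integer(ts$source)
    ts
  })
  spreads <- unlist(variation)
  assert_that(all(spreads >= 0), "variation spreads must be non-negative")
  cfg <- list(n_subjects = as.integer(n_subjects), grid_side = as.integer(grid_side),
              n_sources = as.integer(n_sources), n_timepoints = as.integer(n_timepoints),
              tr = tr, baseline = baseline, cnr = cnr, task_sources = task_sources,
              unique_event_prob = unique_event_prob, psc_mean = psc_mean,
              psc_sd = psc_sd, block_on = block_on, block_off = block_off,
              n_blocks = as.integer(n_blocks), variation = variation,
              seed = as.integer(seed), source_maps = source_maps,
              source_centers = source_centers, source_sigmas = source_sigmas)
  structure(cfg, class = "sim_config")
}

#' Canonical double-gamma haemodynamic response function
#'
#' Peak near 6 s, undershoot near 16 s, undershoot ratio 1/6, sampled at the
#' TR and truncated at 32 s; normalised to unit peak.
#'
#' @param tr sampling interval in seconds.
#' @param duration kernel length in seconds.
#' @return numeric vector of HRF samples.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Default blob atlas geometry: jittered lattice of centers, mildly anisotropic
# Gaussian widths scaled to the grid.
default_atlas <- function(config) {
  g <- config$grid_side
  n <- config$n_sources
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  margin <- g / (2 * max(nrow_, ncol_))
  xs <- seq(margin, g - margin, length.out = nrow_)
  ys <- seq(margin, g - margin, length.out = ncol_)
  centers <- as.matrix(expand.grid(x = xs, y = ys))[seq_len(n), , drop = FALSE]
  spacing <- min(diff(c(0, xs, g))[2], diff(c(0, ys, g))[2], g / 4)
  if (spacing < 4) stop("grid too small to place ", n, " distinct sources")
  # compact blobs: neighbouring sources must stay near-orthogonal spatially,
  # as in SimTB's source atlas, or the maps are not independent sources
  base_sigma <- spacing / 4.5
  jitter <- matrix(rnorm(2 * n, 0, spacing / 12), ncol = 2)
  centers <- pmin(pmax(centers + jitter, margin / 2), g - margin / 2)
  sig_ratio <- rep_len(c(1, 1.15, 0.87), n)
  sigmas <- cbind(base_sigma * sig_ratio, base_sigma / sig_ratio)
  list(centers = centers, sigmas = sigmas)
}

#' Generate the group-level source atlas
#'
#' Builds \code{n_sources} smooth, spatially localised, pairwise-distinct
#' Gaussian-blob maps on the grid, each normalised to unit peak. Centers and
#' widths come from a jittered lattice unless overridden in the config; a
#' user-supplied \code{source_maps} matrix bypasses the atlas entirely.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an \code{n_sources x grid_side^2} matrix (row-major maps, column-major
#'   voxel flattening of the grid).
#' @export
generate_group_sources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid_side
  V <- g * g
  if (!is.null(config$source_maps)) {
    m <- config$source_maps
    assert_that(is.matrix(m) && nrow(m) == config$n_sources && ncol(m) == V,
                "source_maps must be n_sources x grid_side^2")
    return(m / apply(abs(m), 1L, max))
  }
  with_seed(config$seed, {
    atlas <- default_atlas(config)
    centers <- config$source_centers %||% atlas$centers
    sigmas <- config$source_sigmas %||% atlas$sigmas
    xy <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g)))
    maps <- vapply(seq_len(config$n_sources), function(k) {
      dx <- (xy[, 1] - centers[k, 1]) / sigmas[k, 1]
      dy <- (xy[, 2] - centers[k, 2]) / sigmas[k, 2]
      exp(-(dx^2 + dy^2) / 2)
    }, numeric(V))
    t(sweep(maps, 2L, apply(maps, 2L, max), "/"))
  })
}

# Bilinear sampling of a grid image at fractional coordinates; outside -> 0.
bilinear_sample <- function(img, xf, yf) {
  g1 <- nrow(img); g2 <- ncol(img)
  x0 <- floor(xf); y0 <- floor(yf)
  fx <- xf - x0; fy <- yf - y0
  val <- numeric(length(xf))
  for (dx in 0:1) for (dy in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy
    w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    ok <- xi >= 1 & xi <= g1 & yi >= 1 & yi <= g2 & w > 0
    if (any(ok)) val[ok] <- val[ok] + w[ok] * img[cbind(xi[ok], yi[ok])]
  }
  val
}

# Translate/rotate/scale one map about its center of mass (inverse mapping,
# bilinear interpolation, zero outside the grid).
transform_map <- function(map_vec, grid_side, dx, dy, theta_deg, scale) {
  img <- matrix(map_vec, grid_side, grid_side)
  w <- abs(img)
  tot <- sum(w)
  cx <- if (tot > 0) sum(row(img) * w) / tot else (grid_side + 1) / 2
  cy <- if (tot > 0) sum(col(img) * w) / tot else (grid_side + 1) / 2
  th <- -theta_deg * pi / 180  # inverse rotation
  xy <- as.matrix(expand.grid(x = seq_len(grid_side), y = seq_len(grid_side)))
  rx <- (xy[, 1] - cx - dx) / scale
  ry <- (xy[, 2] - cy - dy) / scale
  xs <- cx + cos(th) * rx - sin(th) * ry
  ys <- cy + sin(th) * rx + cos(th) * ry
  bilinear_sample(img, xs, ys)
}

#' Apply per-subject spatial variation to the group sources
#'
#' Each source is independently translated, rotated and scaled with parameters
#' drawn from zero-mean normals with the configured spreads; transforms act
#' about the source's center of mass, out-of-grid content is clipped to zero
#' and interpolation is bilinear.
#'
#' @param group_sources matrix from \code{\link{generate_group_sources}}.
#' @param variation list with \code{translate_sd}, \code{rotate_sd},
#'   \code{scale_sd}.
#' @param seed integer seed for the parameter draws.
#' @param grid_side grid side (defaults to \code{sqrt(ncol(group_sources))}).
#' @param params optional data frame (columns dx, dy, theta, scale; one row per
#'   source) forcing the transform parameters, for testing.
#' @return list with \code{maps} (same shape as input) and \code{params}
#'   (data frame of the drawn parameters).
#' @export
apply_subject_variation <- function(group_sources, variation, seed,
                                    grid_side = NULL, params = NULL) {
  g <- grid_side %||% as.integer(round(sqrt(ncol(group_sources))))
  n <- nrow(group_sources)
  if (is.null(params)) {
    params <- with_seed(seed, data.frame(
      dx = rnorm(n, 0, variation$translate_sd),
      dy = rnorm(n, 0, variation$translate_sd),
      theta = rnorm(n, 0, variation$rotate_sd),
      scale = 1 + rnorm(n, 0, variation$scale_sd)
    ))
  }
  maps <- t(vapply(seq_len(n), function(k) {
    if (params$dx[k] == 0 && params$dy[k] == 0 && params$theta[k] == 0 &&
        params$scale[k] == 1) return(group_sources[k, ])
    transform_map(group_sources[k, ], g, params$dx[k], params$dy[k],
                  params$theta[k], params$scale[k])
  }, numeric(ncol(group_sources))))
  list(maps = maps, params = params)
}

#' Task boxcar regressor
#'
#' @param config a \code{\link{sim_config}}.
#' @return 0/1 vector of length \code{n_timepoints}: \code{block_on/tr} ones
#'   then \code{block_off/tr} zeros, repeated \code{n_blocks} times and padded
#'   with zeros.
#' @export
task_boxcar <- function(config) {
  on_tr <- round(config$block_on / config$tr)
  off_tr <- round(config$block_off / config$tr)
  cycle <- c(rep(1, on_tr), rep(0, off_tr))
  box <- rep(cycle, config$n_blocks)
  c(box, rep(0, config$n_timepoints - length(box)))[seq_len(config$n_timepoints)]
}

#' Generate one subject's source time courses
#'
#' Task-modulated sources receive (boxcar x task amplitude + unique event
#' train x unique amplitude); non-task sources receive unique events of
#' amplitude 1. Neural trains are convolved with the canonical HRF and each
#' time course is then scaled so its peak amplitude equals a percent signal
#' change drawn from N(psc_mean, psc_sd^2) (clipped below at 0.5 percent)
#' relative to the baseline intensity.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return \code{n_timepoints x n_sources} matrix.
#' @export
generate_timecourses <- function(config, seed) {
  nt <- config$n_timepoints
  ns <- config$n_sources
  hrf <- canonical_hrf(config$tr)
  box <- task_boxcar(config)
  task_idx <- vapply(config$task_sources, `[[`, integer(1) , "source")
  with_seed(seed, {
    tc <- matrix(0, nt, ns)
    for (k in seq_len(ns)) {
      events <- rbinom(nt, 1L, config$unique_event_prob)
      ti <- match(k, task_idx)
      neural <- if (!is.na(ti)) {
        ts <- config$task_sources[[ti]]
        box * ts$task_ratio * ts$unique_amp + events * ts$unique_amp
      } else {
        events * 1
      }
      conv <- convolve(neural, rev(hrf), type = "open")[seq_len(nt)]
      psc <- max(0.5, rnorm(1, config$psc_mean, config$psc_sd))
      peak <- max(abs(conv))
      tc[, k] <- if (peak > 0) conv * (config$baseline * psc / 100) / peak else conv
    }
    tc
  })
}

#' Synthesize a full multi-subject dataset with ground truth
#'
#' For each subject: draws per-source spatial variation, builds time courses,
#' forms \code{baseline + TC \%*\% sources}, and adds white Gaussian noise whose
#' sd is set from the CNR (sd of the noise-free signal fluctuation over all
#' in-brain voxels divided by the noise sd equals \code{cnr}).
#'
#' @param config a \code{\link{sim_config}}.
#' @param dataset_id identifier stamped on each subject.
#' @return list with \code{subjects} (list of \code{\link{subject_data}}) and
#'   \code{truth} (class \code{sim_truth}: \code{group_sources},
#'   \code{subject_sources}, \code{timecourses}, \code{variation_params},
#'   \code{seed_used}, \code{config}).
#' @export
synthesize_dataset <- function(config, dataset_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  group <- generate_group_sources(config)
  seeds <- derive_seeds(config$seed, 3L * config$n_subjects)
  subjects <- vector("list", config$n_subjects)
  subj_sources <- vector("list", config$n_subjects)
  tcs <- vector("list", config$n_subjects)
  vpar <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    var_i <- apply_subject_variation(group, config$variation,
                                     seed = seeds[3L * i - 2L],
                                     grid_side = config$grid_side)
    tc <- generate_timecourses(config, seed = seeds[3L * i - 1L])
    signal <- tc %*% var_i$maps
    fluct <- sweep(signal, 2L, colMeans(signal))
    noise_sd <- pop_sd(as.vector(fluct)) / config$cnr
    noise <- with_seed(seeds[3L * i],
      matrix(rnorm(length(signal), 0, noise_sd), nrow(signal)))
    data <- config$baseline + signal + noise
    subjects[[i]] <- subject_data(data, tr = config$tr,
                                  shape = c(config$grid_side, config$grid_side),
                                  subject_id = sprintf("sub%02d", i),
                                  dataset_id = dataset_id)
    subj_sources[[i]] <- var_i$maps
    tcs[[i]] <- tc
    vpar[[i]] <- var_i$params
  }
  truth <- structure(list(group_sources = group, subject_sources = subj_sources,
                          timecourses = tcs, variation_params = vpar,
                          seed_used = config$seed, config = config),
                     class = "sim_truth")
  list(subjects = subjects, truth = truth)
}
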