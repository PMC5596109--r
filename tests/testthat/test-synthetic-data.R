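test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(grid_side = 6), "grid_side")
  expect_error(sim_config(unique_event_prob = 1.2), "unique_event_prob")
  expect_error(sim_config(cnr = 0), "cnr")
  expect_error(sim_config(n_timepoints = 50, block_on = 24, block_off = 24,
                          n_blocks = 5, tr = 2), "block design")
  expect_error(small_config(task_sources = list(list(source = 9L,
                                                     task_ratio = 2,
                                                     unique_amp = 1))),
               "task source")
})

test_that("group sources are unit-peak, distinct, and deterministic in the seed", {
  cfg <- sim_config(n_sources = 12, grid_side = 148, seed = 3)
  maps <- generate_group_sources(cfg)
  expect_equal(dim(maps), c(12, 148^2))
  expect_equal(apply(maps, 1, max), rep(1, 12))
  # pairwise near-orthogonality of the atlas
  C <- abs(cor(t(maps))); diag(C) <- 0
  expect_lt(max(C), 0.2)
  expect_identical(maps, generate_group_sources(cfg))
  cfg2 <- sim_config(n_sources = 12, grid_side = 148, seed = 4)
  expect_false(identical(maps, generate_group_sources(cfg2)))
  # single blob case
  one <- generate_group_sources(small_config(n_subjects = 1,
                                             task_sources = list())
                                |> (\(x) {x$n_sources <- 1L; x})())
  expect_equal(max(one), 1)
})

test_that("subject variation translates, rotates, and degrades gracefully", {
  cfg <- small_config()
  maps <- generate_group_sources(cfg)
  # zero spreads: identity
  v0 <- apply_subject_variation(maps, list(translate_sd = 0, rotate_sd = 0,
                                           scale_sd = 0), seed = 1)
  expect_equal(v0$maps, maps)
  # forced pure translation moves the blob peak by exactly (dx, dy)
  g <- 64L
  xy <- as.matrix(expand.grid(x = 1:g, y = 1:g))
  blob <- matrix(exp(-((xy[, 1] - 50)^2 + (xy[, 2] - 50)^2) / (2 * 9)), 1)
  tr <- apply_subject_variation(blob, NULL, seed = 1, grid_side = g,
                                params = data.frame(dx = 3, dy = 0, theta = 0,
                                                    scale = 1))
  peak <- arrayInd(which.max(tr$maps[1, ]), c(g, g))
  expect_equal(as.vector(peak), c(53, 50))
  # 180-degree rotation of a point-symmetric blob is a no-op
  rot <- apply_subject_variation(blob, NULL, seed = 1, grid_side = g,
                                 params = data.frame(dx = 0, dy = 0,
                                                     theta = 180, scale = 1))
  expect_lt(max(abs(rot$maps - blob)), 1e-4)
})

test_that("task boxcar and time courses follow the block design", {
  cfg <- sim_config(seed = 1)  # 24 s on / 24 s off x 5 at TR = 2
  box <- task_boxcar(cfg)
  expect_equal(length(box), 120)
  expect_equal(box[1:24], rep(c(1, 0), each = 12))
  expect_equal(sum(box), 5 * 24 / 2)  # n_blocks * block_on / tr "on" TRs
  tc <- generate_timecourses(cfg, seed = 9)
  expect_equal(dim(tc), c(120, 12))
  expect_true(all(is.finite(tc)))
  # no events and no task -> flat zero time course
  quiet <- small_config(task_sources = list(), unique_event_prob = 0)
  tc0 <- generate_timecourses(quiet, seed = 2)
  expect_equal(max(abs(tc0)), 0)
})

test_that("time courses are deterministic in the seed and scaled by PSC", {
  cfg <- small_config()
  tc <- generate_timecourses(cfg, seed = 31)
  expect_identical(tc, generate_timecourses(cfg, seed = 31))
  expect_false(identical(tc, generate_timecourses(cfg, seed = 32)))
  # peak amplitude of each course is psc% of baseline; draws center on psc_mean
  peaks <- apply(abs(tc), 2, max) / cfg$baseline * 100
  expect_true(all(peaks > 0.5))
  expect_lt(abs(mean(peaks) - cfg$psc_mean), 4 * cfg$psc_sd)
})

test_that("synthesized data has the stated shape, CNR and determinism", {
  cfg <- small_config(seed = 21)
  d <- synthesize_dataset(cfg)
  expect_length(d$subjects, 3)
  expect_equal(dim(d$subjects[[1]]$data), c(48, 576))
  # bit-identical regeneration
  d2 <- synthesize_dataset(cfg)
  expect_identical(d$subjects[[1]]$data, d2$subjects[[1]]$data)
  expect_identical(d$truth$group_sources, d2$truth$group_sources)
  # empirical CNR: reconstruct noise as data - baseline - signal
  tc <- d$truth$timecourses[[1]]
  sig <- tc %*% d$truth$subject_sources[[1]]
  noise <- d$subjects[[1]]$data - cfg$baseline - sig
  fluct <- sweep(sig, 2, colMeans(sig))
  expect_equal(sd(as.vector(fluct)) / sd(as.vector(noise)), cfg$cnr,
               tolerance = 0.02)
})

test_that("noiseless, variation-free data yields near-perfect ICA recovery", {
  cfg <- small_config(n_subjects = 1, cnr = Inf, seed = 5,
                      variation = list(translate_sd = 0, rotate_sd = 0,
                                       scale_sd = 0))
  d <- synthesize_dataset(cfg)
  m <- fastica(d$subjects[[1]]$data, 4, seed = 2)
  rep <- recovery_report(m$S, d$truth$group_sources)
  expect_true(all(rep$per_source > 0.99))
})
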