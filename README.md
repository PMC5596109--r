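# fmica

Hierarchical feature-map ICA for identifying brain functional networks
(BFNs) across one or more fMRI datasets.

Conventional group ICA concatenates raw time series across subjects, which
scales poorly and handles heterogeneous datasets (different TR, scanner,
session structure) awkwardly. `fmica` instead carries only **feature maps**
— each subject's spatial independent-component maps — between analysis
levels, and delivers networks at four scales:

- **subject** — each subject's own ICA maps (level-1 spatial ICA on
  `X = AS`, estimated by fixed-point negentropy FastICA after PCA
  whitening);
- **intragroup** — ICA on the stacked subject maps of one dataset
  (level 2);
- **intergroup** — ICA on the stacked intragroup maps across datasets
  (level 3, `m ≥ 2` datasets);
- **intragroup-specific / subject-specific** — constrained ICA (ICA-R /
  GIG-ICA style) re-estimation, solving

  maximize J(y) subject to ε(y, r) − ξ ≤ 0 and E(y²) = 1,

  where J is the negentropy contrast, r a z ≥ 1 thresholded reference map
  from the level above, and ε(y, r) = −|corr(y, r)| the closeness.

Model order is chosen per level: Minka's Laplace-approximation evidence on
the covariance eigenspectrum (level 1), the rounded mean subject order
(level 2), and the averaged count or ICASSO stability selection (level 3).
Delivered maps are z-scored SPMs thresholded at z ≥ 2.0 with clusters
smaller than 10 voxels removed.

The package includes a SimTB-style multi-subject simulator
(block-design task convolved with a canonical double-gamma HRF, unique
events, per-subject spatial variation, CNR-controlled noise) so that every
stage is testable against known ground truth.

## Worked example

Simulate a small cohort, run the two ICA levels plus the constrained
re-estimation, and score everything against the generator's ground truth:

```r
library(fmica)

cfg <- sim_config(n_subjects = 8, grid_side = 64, n_sources = 6,
                  n_timepoints = 100, block_on = 24, block_off = 24,
                  n_blocks = 2,
                  task_sources = list(list(source = 6, task_ratio = 4,
                                           unique_amp = 0.25)),
                  seed = 11)
sim <- synthesize_dataset(cfg)
sim$subjects[[1]]
#> <subject_data sim/sub01: 100 time points x 4096 voxels, TR=2s, grid 64x64>

sets <- first_level(sim$subjects, order = 7, seed = 1)   # 6 sources + noise
gics <- second_level(aggregate_maps(sets), order = 6,
                     dataset_id = "sim", seed = 2)
gics
#> <feature_map_set [intragroup sim]: 6 maps x 4096 voxels>

recovery_report(gics, sim$truth$group_sources)$per_source
#> 0.973 0.987 0.980 0.983 0.972 0.984        # mean 0.980, sd 0.006
```

Each intragroup map correlates 0.97–0.99 with the spatial source that
generated the data. Constrained re-estimation then recovers per-subject
versions of each network, and improves on standalone per-subject ICA for
every subject:

```r
ss <- reestimate_specific(sets, gics, z_ref = 1.0, seed = 3)
fm <- sapply(1:8, function(i)
  recovery_report(ss[[i]], sim$truth$subject_sources[[i]])$mean)
pl <- sapply(1:8, function(i)
  recovery_report(sets[[i]], sim$truth$subject_sources[[i]])$mean)
sum(fm > pl)
#> 8                                          # improved subjects, of 8

threshold_clusters(zscore_map(gics$maps[1, ]), shape = c(64, 64))
#> <bfn_map: 126 voxels in 1 cluster(s) at z>=2, min cluster 10>

estimate_order_laplace(sim$subjects[[1]]$data, 30)
#> <order_estimate (laplace): chosen 6 of candidates 1..30>
```

The Laplace estimator recovers the planted source count from the raw data.
For multi-dataset runs, `run_fmica()` orchestrates all levels from a named
list of datasets and a `fmica_config()`; with a single dataset it skips the
intergroup stage and uses the intragroup maps as subject-specific
references. A command-line wrapper (`inst/cli/fmica.R`) exposes
`simulate`, `run`, and `evaluate` subcommands over NIfTI/YAML/JSON files.

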