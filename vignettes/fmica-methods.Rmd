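---
title: "Hierarchical feature-map ICA: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical feature-map ICA: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fmica)
```

## The problem

Group ICA of fMRI traditionally concatenates raw time series across
subjects, which becomes unwieldy when datasets differ in repetition time,
scanner, or session structure, and scales poorly with cohort size. The
framework implemented here replaces raw time series with *feature maps* —
each subject's spatial independent-component maps — as the only quantity
carried between analysis levels. Three levels of spatial ICA (subject,
intragroup, intergroup) are chained, and constrained ICA with spatial
references (ICA-R, in the GIG-ICA style) re-estimates dataset-flavoured
(*intragroup-specific*) and individual (*subject-specific*) versions of each
network. Delivered networks are z-scored statistical parametric maps (SPMs)
thresholded with cluster-size control.

## Models

**Linear ICA.** Each subject's data is modeled as $X = AS$ with $X$ the
time-by-voxel matrix, $S$ the spatially independent source maps, and $A$ the
mixing (time-course) matrix; estimation finds an unmixing $W$ with $Y = WX$.
We use fixed-point negentropy maximisation (FastICA) with symmetric
decorrelation after PCA whitening. The contrast is $G(u) = \log\cosh u$ by
default (`pow3`, i.e. kurtosis, is available). Components are sign-fixed to
positive skewness — activation maps are right-skewed — and ordered by
variance explained in the original space.

**Constrained ICA (ICA-R).** For a reference map $r$, the extraction solves

$$\max J(y) \quad \text{s.t.}\; g(y) = \varepsilon(y, r) - \xi \le 0,\;
h(y) = E(y^2) - 1 = 0,$$

where $J$ is the negentropy contrast and $\varepsilon(y,r) =
-\lvert\mathrm{corr}(y, r)\rvert$ is the closeness (smaller is closer; sign-
and scale-invariant by construction; a mean-squared-error closeness was
considered and rejected because ICA components carry arbitrary sign and
scale). The unit-variance constraint is enforced exactly by optimising a
unit-norm vector in the whitened mixture space, where the correlation with
the standardised reference is *linear* in the weight vector — the feasible
region is a cone around the reference's projection.

**Hierarchy.** Level 1 decomposes each subject (order from the Laplace
estimator unless fixed). Level 2 stacks one dataset's subject maps
(rows = observations, voxels = samples, the feature-based group-ICA
convention), PCA-reduces the rows to the target order and runs ICA; the
order is the rounded mean of the subject orders. Level 3 does the same
across datasets; its order is the rounded average of the per-dataset
component counts when the datasets are sessions of the same subjects, and
otherwise chosen by ICASSO stability over the range [min, max] of those
counts. ICA-R then re-estimates intragroup-specific maps (intragroup
mixtures, intergroup references) and subject-specific maps (subject
mixtures, references from the intragroup-specific maps by default, the
intergroup maps by option). With a single dataset ($m = 1$) there is no
third level and no intragroup-specific stage; the intragroup maps are the
subject-specific references.

## Order selection

*Laplace approximation.* The per-subject order maximises Minka's
Laplace-approximation evidence for probabilistic-PCA dimensionality on the
eigenspectrum of the sample covariance. When channels outnumber samples the
smaller-dimension covariance is used (the nonzero eigenvalues agree). On the
standard simulation (12 sources, white noise, constant baseline removed by
centering) it selects 12–13.

*Mean order.* Arithmetic mean across subjects, rounded half-up. Half-up is
a convention choice; the rule is otherwise stated only as "the mean".

*ICASSO.* For each candidate order, `n_runs` randomised restarts are pooled
and clustered by $1 - |\mathrm{corr}|$ dissimilarity (average-linkage
agglomeration cut at the candidate order). Each cluster scores
$I_q = \overline{\text{within-cluster similarity}} -
\overline{\text{between-cluster similarity}}$; the chosen order maximises
mean $I_q$, with smaller sd and then smaller IQR as tie-breaks. Restarts
only — no bootstrap resampling — since stability across runs is what the
selection rule consumes. A caveat worth knowing: on clean, well-separated
synthetic data the fixed-point iteration converges to the same optimum from
nearly any initialisation, so restart-only stability saturates near 1 at
every order and the selection rests on small differences; the measure is
discriminative when noise makes the optimisation landscape ambiguous, which
is the regime it was designed for.

## The constrained-ICA solver and the closeness bound

Each reference is processed independently (one-unit extraction), so
references never compete. The weight vector is initialised at the whitened
projection of the standardised reference — the max-correlation solution —
and refined by a one-unit fixed-point (Newton-like) negentropy step combined
with an augmented-Lagrangian multiplier on the closeness constraint; a final
exact feasibility restoration places the iterate on the constraint boundary
when the solver drifted outside a satisfiable bound.

The bound $\xi$ matters more than it looks. With a loose fixed bound
(e.g. $\xi = -0.5$), pure negentropy ascent converges to the mixture's own
ICA fixed points: the "re-estimation" then merely reproduces the subject's
unconstrained components and the group information in the reference is
discarded. The default is therefore *adaptive*: per reference,
$\xi_j = -(\text{correlation attained by the initial projection}) +
\texttt{xi\_slack}$, floored at $-0.5$, with `xi_slack = 0.02`. This keeps
the solution inside a small cone around the best reference-matching
combination while negentropy is maximised within it — which is how group
references denoise individual maps, and is the behaviour that makes the
subject-specific maps beat standalone per-subject ICA on simulated ground
truth (20 of 20 subjects in the packaged study). A numeric $\xi$ passed
explicitly is honoured as given for all references; infeasible bounds flag
`constraint_violated` rather than failing.

## The simulator

`sim_config()` defaults encode the study conditions the package validates
against: 20 subjects; a $148 \times 148$ voxel slice; 12 sources; 120 time
points at TR = 2 s; baseline intensity 800; contrast-to-noise ratio 1;
block-design task (24 s on, 24 s off, five cycles) convolved with a
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, unit
peak); unique events with probability 0.2 per TR; percent signal change
drawn per time course from $N(3, 0.25^2)$ (clipped below at 0.5%) relative
to baseline; sources 10 and 12 task-modulated with task-to-unique amplitude
ratios 4 and 2 and unique amplitudes 0.2 and 0.4; unique amplitude 1
elsewhere.

Choices where the emulated toolchain leaves gaps:

- **Source atlas.** Gaussian blobs on a jittered lattice, mildly
  anisotropic, unit peak. Widths are set to `spacing / 4.5` so that
  neighbouring sources stay near-orthogonal (max pairwise spatial
  $|r| < 0.1$): spatial ICA's premise is independent maps, and wide
  overlapping blobs silently break it — in early drafts this overlap, not
  noise, was the limit on recovering the temporally collinear task pair.
  User-supplied maps (`source_maps`) replace the atlas entirely.
- **Subject variation.** Per source and subject: translation
  $N(0, 1.5^2)$ voxels per axis, rotation $N(0, 3^2)$ degrees, scale
  $1 + N(0, 0.03^2)$, applied about the source's centre of mass with
  bilinear interpolation, clipped at the grid boundary. The spreads are
  realistic-modest stand-ins (the emulated experiment documents its spreads
  only in unavailable supplementary material) and are fully configurable.
- **CNR.** Noise sd is set so that (sd of the noise-free signal fluctuation
  over all in-brain voxels) / (noise sd) equals the configured ratio,
  per subject — an amplitude-ratio convention.
- **What is not modelled.** 3-D anatomy, physiological noise spectra,
  motion, scanner drift, spatial smoothness of noise. Passing tests on this
  generator shows the machinery is correct under the stated generative
  model, not that real-data performance follows.

## Delivered networks

Feature maps are z-scored over in-mask voxels with the population (1/N) sd
(the map then has mean 0, sd 1 exactly), thresholded one-sided at
$z \ge 2.0$, and labeled into connected clusters (8-connectivity in 2-D,
26 in 3-D — the common neuroimaging convention; the choice is undocumented
in the emulated procedure). Clusters under 10 voxels are removed. References
for ICA-R use the same z-scoring with the milder threshold $z \ge 1.0$.
Raising either threshold can only shrink the surviving voxel set
(monotonicity), and re-thresholding a delivered map with the same
parameters is a no-op.

## Numerical conventions

- Whitening uses the population covariance; eigenvalues below
  $10^{-10} \times \lambda_{\max}$ define numerical rank, and a requested
  order above the rank is reduced with a warning.
- FastICA: tol $10^{-6}$ on $\max\,\bigl|\,|\langle w_{new}, w_{old}\rangle|
  - 1\bigr|$, max 1000 iterations; non-convergence returns the best iterate
  flagged, and ICASSO excludes non-convergent runs from pooling.
- Component matching (for evaluation only) is greedy on descending $|r|$
  without replacement; an exhaustive optimal assignment is available for up
  to 9 templates. On near-permutation correlation structures — the regime
  where matching is meaningful — the two agree.
- Welch's $t$ is the default two-sample contrast; equality of variances is
  not assumed.
- All randomness is seeded; per-stage sub-seeds derive from the master seed,
  so identical (data, config, seed) reruns are bit-identical.

## Problem sizes used in the packaged validation

The packaged study runs the full stated conditions (20 subjects of
$120 \times 21904$, orders 13/13). Unit and property tests use reduced
conditions (grids 16–64, 3–5 sources, 2–6 subjects) chosen so every stage
still operates away from degeneracy; oracle comparisons (rotation grid
search for 2-source ICA, flood-fill cluster labeling) run at sizes where the
oracle is exact and fast.

## Known limitations

- The intergroup level is validated structurally and on reduced synthetic
  data; the headline multi-dataset results of the original study depend on
  real test-retest cohorts outside this package's scope.
- Restart-only ICASSO saturates on clean data (above); with strongly
  non-Gaussian, low-noise inputs prefer the Laplace or mean-order rules.
- One-sided positive thresholding only; deactivation clusters are not
  delivered.
- Real-data preprocessing (slice timing, realignment, normalisation,
  smoothing) is out of scope: inputs are assumed pre-registered, and
  affines are carried through untouched.
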