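---
title: "Methods: latent-input network modeling of brainstem and spinal cord BOLD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-input network modeling of brainstem and spinal cord BOLD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapmnet)
```

## The model

`sapmnet` implements structural and physiological modeling (SAPM) of
blood-oxygenation-level-dependent (BOLD) fMRI time-courses across a
predefined anatomical network, here the descending pain-regulation
circuitry of the brainstem, diencephalon and cervical spinal cord.  The
network is a directed graph over ten regions (C6RD, DRt, Hypothalamus,
LC, NGc, NRM, NTS, PAG, PBN, medial Thalamus) with 32 inter-region
connections and 3 latent ("intrinsic") inputs entering from outside the
network — 35 connections in total.

Each region's output signaling $O_r(t)$ is the sum of its weighted
inputs:

$$O_r(t) \;=\; \sum_{s \to r} \beta_{sr}\, O_s(t) \;+\; \sum_{j \to r} m_{jr}\, L_j(t),$$

in matrix form $O = A\,O + M L$, solved exactly as
$O = (I-A)^{-1} M L$ when the spectral radius of $A$ is below 1
(`forward_model()` refuses unstable weight sets).  The signed weights
$\beta_{sr}$ are the connectivity *DB values*: positive weights are
excitatory (more input produces more output), negative weights
inhibitory.  The *D shares* reported by `derived_D()` are the derived
per-source normalization $|\beta_{sr}| / \sum_{r'} |\beta_{sr'}|$,
describing how a region's output is apportioned among its targets.  The
model treats a region's modeled BOLD response and its output signaling
as the same summed-input signal; no hemodynamic deconvolution is
attempted, and the separate estimation of distinct D and B matrices used
in earlier formulations of the method is out of scope here (the single
product weight per connection is what the group statistics operate on).

### Assumptions

* Signaling is linear and instantaneous at the volume (TR) time scale;
  all temporal structure enters through the latent inputs.
* The anatomical graph is known a priori; only weights, latent
  time-courses and the sub-region choice are estimated.
* The latent inputs are smooth BOLD-like trajectories; each latent
  enters the network at its declared target region(s).
* Weight sets are stable (spectral radius of $A$ strictly below 1).

## Fitting

`fit_sapm()` uses alternating least squares on each participant's
(run-averaged, mean-centered) region time-courses:

1. given the latent time-courses, each region is regressed by ordinary
   least squares on the *observed* series of its source regions plus its
   latent links (conditional-linear scheme);
2. given the weights, each latent time-course is re-estimated by least
   squares over its target-region residual system, then recentered and
   rescaled to zero mean and unit variance, with the scale absorbed into
   its link weights.

Total SSE is non-increasing across iterations; iteration stops when the
relative SSE change falls below `tol` (default `1e-6`, maximum 200
iterations), and the best of `n_restarts` (default 5) random latent
initializations is kept.  The sign indeterminacy of each latent
(flipping $L_j$ and its outgoing weights leaves the fit unchanged) is
resolved by forcing the weight onto the latent's first declared target
to be non-negative.  Rank-deficient source sets fall back to the
minimum-norm solution with a warning.

### Why latents are basis-constrained

Each latent in the packaged network has exactly one target (the
35-connection total pins one link per latent).  A *free-form* latent
with a single target can reproduce that region's residual exactly, which
drives the region's SSE to zero after one step and leaves its incoming
DB weights completely unidentified.  Latent time-courses are therefore
restricted by default to a 12-component zero-mean discrete-cosine basis
(`n_latent_basis` in `sapm_fit_opts()`), which spans slow BOLD-like
trajectories over a 40-volume run while leaving the innovation-scale
variation of the source series available for weight identification.
With single-target latents the resulting objective is an ordinary joint
least-squares problem with a unique optimum, so the alternating scheme
converges in a few iterations and restarts merely reproduce the same
solution.  `n_latent_basis = NULL` restores free-form latents for
networks whose latents have several targets.  Simulation checks during
development showed weight recovery is unbiased for basis sizes 6-20;
12 is the shipped default.

### Why generator noise propagates through the network

The synthetic generator models noise as per-region *innovations* that
enter the network equation, $X = (I-A)^{-1}(ML + E)$, rather than as
noise added after the fact to the deterministic forward solution.  This
is the standard structural-equation convention, and it is what makes the
estimation problem well-posed for the published ground truth: under the
published FM weights, PBN's only input is LC, so with purely
observational noise the PBN signal is exactly collinear with LC and no
estimator could apportion the thalamic input between them (the
likelihood is flat along a ridge).  With propagated innovations every
region carries its own exogenous variation, the per-region regression
equation holds exactly in the observed series, and the
conditional-linear estimator is consistent.  At `noise_sd = 0` both
conventions coincide with the deterministic forward model bit-for-bit.
The `noise_model = "additive"` option retains the literal
observation-noise variant for comparison.

## The synthetic world

The generator emulates the study design rather than any particular
dataset:

| parameter | default | meaning |
|---|---|---|
| run duration | 270 s | one imaging run |
| TR | 6.75 s | seconds per volume (40 volumes/run) |
| runs per condition | 5 | run-averaged series are generated directly |
| cue | 3-s boxcar at 60 s | condition announcement |
| stimulation | 10 contacts, 1.5 s, onsets every 3 s from 120 s | Pain runs only |
| temperatures | 46, 50, 44, 48 degC | one per Pain run |
| `noise_sd` | 0.2 | innovation SD, relative to unit-variance latent drives |
| attenuation | 0.3 | signal leakage into non-signal sub-regions |
| `n_per_group` | 15 | participants per group |
| first-contact rating | FM 41.6 +/- 14.2, HC 24.6 +/- 14.4 | truncated to the 0-100 pain scale |

Three neural components drive the latents: the stimulation boxcars
(into the spinal dorsal horn), the cue transient (into the LC, arousal)
and a tonic half-cosine drift (into the thalamus).  Each is convolved
with a canonical double-gamma hemodynamic response (unit peak near 5 s)
at 0.25-s resolution — chosen because it divides the TR exactly — then
volume-sampled and standardized.  Participant-level weights are drawn
once per connection from
$\mathcal{N}(\mu_c, \sigma_c)$ where $\mu_c$ is the published
group/condition mean and $\sigma_c$ the printed spread times
$\sqrt{15}$: the published "$\pm$" values behave as standard errors
(mean/$\pm$ reproduces the printed T statistics at $n = 15$), so the
between-participant SD is their $\sqrt{n}$ multiple.  Unreported
connections have mean 0 and SD 0.  Draws are rejected and redrawn
(deterministically) if their spectral radius reaches 0.95, since the
model class itself requires stability.  Ratings for the last contact add
a group-specific temporal-summation increment (HC +12.2, FM +4.5, the
differences of the published group means; SD 8).

What a green test does **not** establish: the generator has no
physiological (cardiac/respiratory) noise, no scanner drift or motion,
no temperature-calibration variability, and the run average is emitted
directly rather than averaging five simulated runs.  Parameter-recovery
results therefore validate the estimator against its own generative
class, not against real-data artifacts; the published group tables are
from an undeposited cohort and are used only as ground-truth settings,
never as values the pipeline is expected to reproduce from data.

## Sub-regions

Each region is divided into five near-equal-volume sub-regions by
k-means on voxel coordinates (0-based indices; clustering on
coordinates, not time-courses, because near-equal *volume* is a spatial
criterion).  Vanilla k-means does not guarantee balance, so voxels are
greedily reassigned from over-full clusters to the nearest under-full
centroid until the largest cluster is within `balance_tol` (default
0.25) of the mean size; ties break toward the lowest cluster index and
the result is deterministic given the seed.  One sub-region per region
enters the fit; `select_subregions()` maximizes total variance explained
by exhaustive enumeration for four or fewer regions and greedy
coordinate ascent with restarts otherwise, with ties again breaking to
the lowest index.

## Statistics

Group inference follows the published workflow: per-connection
one-sample t-tests of the group DB values against a null reference —
the mean weight obtained by refitting phase-randomized surrogates of the
region series (amplitude spectra preserved to numerical tolerance,
paradigm locking destroyed) — with Bonferroni correction over the 32
inter-region connections ($0.05/32 = 0.0015625$, displayed 0.00156).
The significance threshold is the *one-sided* upper-tail t quantile at
df $= n-1 = 14$, which reproduces the published T-threshold 3.563; the
flag is applied symmetrically as $|T| \ge$ threshold, and the reported
p-value is the upper-tail probability of $|T|$ so the p-rule and
threshold-rule agree exactly.  The null reference enters through its
mean only; regression of weights on pain ratings uses ordinary least
squares with the first-contact rating as the default covariate, and the
group-by-rating ANCOVA uses type-III style partial F tests under
sum-to-zero coding so the interaction p-value is invariant to group
labeling.

## Numerical choices and edge cases

* Convergence: relative SSE tolerance `1e-6`, maximum 200 iterations,
  5 restarts — chosen to pass the grid-search oracle suite with margin.
* Degenerate fits: $R^2$ values are clipped to $[0, 1]$; regions with no
  inputs contribute their full variance to the unexplained pool.
* Zero-variance series (e.g. the stimulation component in No-Pain runs)
  are left as exact zeros rather than standardized.
* Surrogates preserve the DC and (for even lengths) Nyquist bins'
  realness; a constant series maps to itself.
* Stage seeds in the pipeline are pure 31-bit hashes of
  (master seed, stage, participant, condition), so any subset of the
  pipeline can be reproduced in isolation.

## Limitations

* The exact 32-edge set of the published network figure is not
  machine-readable; 21 of the 32 packaged edges are plausible
  descending-pain-modulation pathways tagged `provenance: fixture` in
  `inst/networks/fm_brainstem_cord.yaml`, alongside the 11 edges named
  in the text and tables.
* One signed weight per connection is estimated; the original two-matrix
  (D, B) factorization is reported only as the derived per-source share.
* Latent count and targets are fixed by the network specification;
  whether the original analysis constrained latent trajectories is
  unknown, and the cosine-basis default is this package's own
  regularization choice.
* Run handling: averaging (not concatenation) of the five runs per
  condition is assumed throughout.
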