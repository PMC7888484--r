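---
title: "Stimulus-evoked dynamics and dynamically responsive networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-evoked dynamics and dynamically responsive networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drnkit)
```

## The model

`drnkit` studies how a brain-wide network shapes the response to focal
stimulation.  The structural substrate has two scales:

* **Short-range coupling** on the triangulated cortical sheet: a
  homogeneous, isotropic Gaussian kernel
  $g(d) = \exp(-d^2 / 2\sigma^2)$ over the geodesic distance $d$ along
  the mesh, truncated at $8\sigma$ and row-normalized to unit mass (the
  discrete form of $\int g = 1$).  The two hemispheres are separate
  meshes, so short-range weights never cross the midline.  Geodesic
  rather than chordal distance is used because intracortical fibres
  follow the sheet; on the gently curved synthetic patches the two are
  nearly identical, and the brute-force test oracle uses the same
  metric.
* **Long-range coupling** between areas: a directed, non-negative
  weight matrix $C$ (rows are targets) with conduction delays
  $d_{ij}/v$ from inter-areal distances and a finite speed $v$
  (mm/ms $\equiv$ m/s).  The source signal is the *mean* first state
  variable over the source area's nodes; the target indicator delivers
  the same input to every node of the target area.  The matrix is
  rescaled by one global factor so that the maximum in-strength
  (row sum) is exactly 1.

Unity maximum in-strength is what keeps the network *subcritical*: each
node is a two-variable flow

$$\dot\psi_1 = \eta(\psi_2 - \gamma\psi_1 - \psi_1^3 + u + c),\qquad
  \dot\psi_2 = -\eta\,\varepsilon\,\psi_1,$$

a stable focus next to an Andronov–Hopf bifurcation.  With the default
parameters ($\eta = 76.74\,\mathrm{s^{-1}}$, $\gamma = 1.21$,
$\varepsilon = 12.3083$) the linearized natural frequency is
$\eta\sqrt{\varepsilon - \gamma^2/4}/2\pi \approx 42$ Hz, in the gamma
band; `natural_frequency()` checks this anchor.  Because the coupling
gain can never exceed the local dissipation ($\gamma > 1$), every
stimulated run decays back to rest — the property tests assert the tail
amplitude falls below 1% of the peak.

The balance parameter $\alpha \in [0,1]$ scales the short-range term by
$\alpha$ and the long-range term by $1-\alpha$: $\alpha = 1$ is a purely
locally coupled cortex, $\alpha = 0$ a purely heterogeneously coupled
area network.

## Stimulation and integration

A stimulus is a uniform rectangular pulse of one characteristic time
$\eta^{-1} \approx 13$ ms delivered to every node of the target area (or
a focal disc), with amplitude in units of $\eta$.
`calibrate_stimulus()` finds the amplitude for which an isolated node
peaks at $|\psi_1| = 1$.

Integration uses Heun's method with a 40 µs step for (by default) one
second.  Numerical choices that matter:

* Delays are rounded to integer multiples of `dt`; delayed area means
  live in a ring buffer initialized at the resting fixed point, so a
  run without stimulus is identically zero to machine precision.
* The corrector stage reads the delayed buffer at $t + \Delta t - d$
  (and the predictor state for zero-step delays).  Evaluating both
  stages at $t - d$ looks simpler but leaves a first-order error in the
  delayed terms of order $10^{-3}$ on millimetre-scale toys — an order
  of magnitude above the $10^{-4}$ agreement we require against
  independent references (a fine-step method-of-steps integrator and
  `deSolve::dede`).
* The rectangular pulse enters each step through its exact overlap
  fraction with the step interval.  Edges that do not land on the grid
  otherwise contribute an $O(\Delta t)$ error ($\approx 8\times10^{-3}$
  at the default amplitude), which would dominate every comparison.
* Short-range transmission is instantaneous; only the long-range terms
  are delayed.

The *induced* response subtracts the isolated-node response from the
stimulated nodes, leaving the part of the activity caused by the
network.

## From responses to DRNs

For each trial the node-by-node covariance of the induced response over
250–750 ms after onset is eigen-decomposed; the leading components
covering 99% of variance (at most three) form the
stimulation-site-specific pattern (ss-DRN).  Patterns carry a
deterministic sign (largest-magnitude entry positive).  Similarity
between two ss-DRNs is the mean absolute dot product of rank-matched
components — absolute, because principal components have arbitrary
sign, and rank-matched as the simplest convention when nothing favours
re-pairing.

Trials are clustered by k-means (50 seeded restarts) on the rows of the
pairwise similarity matrix, with the cluster count chosen by the
Tibshirani gap statistic (50 uniform reference sets over the feature
bounding box; smallest $k$ with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$).

One degenerate regime needs care.  Noise-free deterministic runs that
share a structural block collapse, late in the window, onto the block's
slowest mode, so their similarity profiles are *duplicates* up to
numerical noise ($\sim 10^{-5}$).  k-means dispersions are then at the
noise floor, $\log W_k$ is dominated by noise structure, and the gap
rule runs away to the largest candidate $k$.  `select_k_gap()`
therefore collapses profiles identical to within a relative tolerance
of $10^{-3}$ first and, when no more than `max(k_range)` distinct
profiles remain, returns their count — the distinct profiles *are* the
clustering.  Continuous data never trigger the guard (any
within-cluster scatter above the tolerance follows the standard path,
as the Gaussian-blob tests check).

Each cluster becomes a DRN by rotating every member's (zero-padded)
three-component basis onto the member with the highest mean similarity
— the Kabsch solution from the SVD of the cross-covariance with
determinant correction — then averaging columnwise and re-normalizing.
Ties for the basis go to the first member; the result is invariant to
member order and to component sign flips, which the rotation absorbs.

Recurring motifs are connected components of the graph whose edges are
significantly correlated DRN component pairs (Pearson, two-sided,
Bonferroni over the total number of components at the 1% level), tiered
as strong ($r > 0.8$), good ($0.6 < r \le 0.8$) and moderate
($0.5 < r \le 0.6$).

## Structural statistics and comparisons

`graph_measures()` computes in/out/total degree and strength and the
weighted-directed (Fagiolo) clustering coefficient on the long-range
matrix.  Response patterns are compared with structural predictors by
Pearson or Kendall correlation or the Bhattacharyya coefficient, with
seeded permutation nulls (labels shuffled; p floor $1/(n_{perm}+1)$)
and Bonferroni correction by the announced family.

Functional-network templates encode per-area contribution levels
none/medium/high as $0/0.5/1$ (any strictly monotone encoding is
admissible; the midpoint is symmetric), unit-normalized.  DRN components
are coarse-grained to areas by summing squared entries within each area
and re-normalizing, then compared by Pearson and Bhattacharyya with the
family size #templates × 3.

A sensory pathway is an ordered edge list $r_l = (j \to i)$.  Each edge
is scored
$q_l = c_{ij}^2 / (s^{in}_i s^{out}_j)$ (strength mode) or
$q_l = c_{ij}^2 / (\max^{in}_i \max^{out}_j)$ (max mode, always
$\le 1$), and the pathway's embedding is the mean $q_l$.  Response
spread is summarized by the ranked areas that jointly exceed 99% of the
response energy ($\int \psi_1^2\,dt$ over 0.2–0.8 s after stimulation,
strict inequality, so equal energies over 100 areas need all 100), and
bilateral symmetry by the sign of a significant correlation between
homolog-ordered left and right activity.

## The virtual dye-imaging observer

The observer links $\psi_1$ (a mean postsynaptic potential) to what a
voltage-sensitive-dye camera sees: the Hilbert envelope (FFT analytic
signal) removes the gamma oscillation; visible vertices (outward normal
toward the camera) project orthographically onto a focal plane placed
1 mm below the surface and are binned into a square pixel grid (128² at
full scale); fluorescence becomes percent $\Delta F/F_0$ against the
pre-stimulus baseline.  A region activates when its signal first
*strictly* exceeds 20% of its post-stimulus peak, with linear
interpolation between frames; silent regions are excluded.  Regions
ordered by onset (ties by index) form an activation sequence.

Two sequences are compared by the seven-step procedure: drop the first
(stimulated) element, keep length-$L$ prefixes, substitute the
non-overlapping elements of the second prefix pairwise in order of
appearance by those of the first, take one minus the normalized Kendall
transposition distance, and scale by the shared fraction of the
original prefixes.  The distance can optionally be rounded to two
decimals (`distance_digits = 2`) to match the reporting convention of
the worked examples — note those examples are internally inconsistent
(one uses the exact $2/3$, another the rounded $0.67$), so the exact
value is the default and the rounding is opt-in.  Whether the step-4
substitution makes the measure exactly symmetric is not settled;
`sequence_similarity()` reports what it computes and the tests bound
the asymmetry on random inputs instead of hiding it.
`similarity_benchmark()` takes per-row percentiles (50/75/90) of the
within-condition similarity matrix as expectation thresholds and
binarizes a cross-condition matrix against them.

## What the synthetic data emulate — and what they do not

The generators provide every input the pipeline needs without an
external atlas: two mirror-image rectangular spherical cortical patches
(regular strip triangulation, analytic normals), a seeded k-means
parcellation copied across hemispheres so areas come in exact homolog
pairs, interior subcortical centroids, and a long-range connectome
drawn log-normally (location 0, scale 1) at a chosen density on the
right-target blocks and mirrored through the homolog permutation —
exactly invariant under swapping left and right.  Delays derive from
centroid Euclidean distances, since synthetic data has no tracts.  The
defaults (200 vertices and 6 cortical + 4 subcortical areas per
hemisphere, density 0.6, 1 m/s) are a deliberate desk-scale model of
the real system's 13,972 vertices and 512 areas; the sweep arithmetic
(18,432 trials; 28,800 state variables) is checked at the printed
scale, the dynamics at the small one.

The planted-cluster fixture trades realism for an exact ground truth:
blocks are spatially compact groups of areas (k-means on centroids),
uniformly all-to-all coupled within a block with inter-block weights at
1% (the regime in which recovery is claimed), so each block carries one
collective slow mode and every stimulation inside a block converges to
it.  The fixture spec uses a high conduction speed: with
millisecond-scale delays the slow mode of a block is a complex pair and
each site excites a differently phase-rotated pattern within it, which
is genuine response structure but fragments the planted labels the
fixture is meant to define.  Passing the planted-recovery test
therefore shows the decomposition–similarity–gap–k-means–alignment
chain is wired correctly; it does not show the clustering would be this
clean on heterogeneous, delay-rich data, where cluster structure is a
matter of degree.

The synthetic dye stacks are ramp-and-decay transients with known
onsets in a tiled pixel grid plus i.i.d. Gaussian noise — no optics,
scattering, photobleaching or registration error, so onset-recovery
tests validate the 20%-rule implementation, not robustness to real
imaging artefacts.

## Problem sizes and costs

The test-suite models use 60–72 vertices and 12–36 areas per model with
the full 40 µs step over 0.8–1 s horizons; the ten-seed planted
recovery runs 36 stimulations per seed.  These sizes make every
property suite run in minutes on one CPU while exercising the same code
paths as a full-scale model; nothing in the implementation is
specialized to the small sizes.

## Known limitations

* Deterministic, noise-free dynamics only: no stochastic resting-state
  mode, no BOLD/EEG forward models.
* The delay buffer quantizes delays to the integration step; delays
  shorter than one step become instantaneous.
* The gap-statistic guard assumes duplicate profiles signal degeneracy;
  data with genuine clusters tighter than $10^{-3}$ relative scatter
  would be collapsed (not observed outside noise-free synthetic runs).
* The observer ignores occlusion beyond the surface-normal visibility
  test (infinite focal length) and does not model the point-spread
  function.
* `run_pipeline()` caches per-trial results keyed by a configuration
  hash; it resumes but does not parallelize.
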