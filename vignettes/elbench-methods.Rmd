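---
title: "Methods: simulating and scoring conformational-heterogeneity benchmarks"
author: "elbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring conformational-heterogeneity benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbench)
```

Methods that recover continuous conformational motion from single-particle
cryo-EM images — multi-body refinement, linear subspace analysis,
variational autoencoders, manifold embedding — are hard to compare on real
data because the true conformational distribution is unknown. `elbench`
provides the two halves of a controlled comparison: a forward model that
generates particle images from a *known* conformational energy landscape,
and an evaluation suite that scores any recovered per-particle embedding
against that ground truth. This vignette documents the model, the defaults
and why they were chosen, the numerical decisions, and the limits of what
the synthetic data can show.

## The ground-truth energy landscape

Conformational space is the unit square spanned by two collective
coordinates $(c_1, c_2)$, each realized physically as a rigid rotation
angle of the small ribosomal subunit (next section). The energy surface is
a flat background minus a sum of Gaussian wells,

$$E(c) \;=\; E_0 \;-\; \sum_{i=1}^{12} d_i
  \exp\!\left(-\frac{\lVert c - \mu_i\rVert^2}{2 w_i^2}\right),$$

with depths $d_i > 0$ and widths $w_i$ in conformational-coordinate units,
and all energies in units of $kT$. A Gaussian-well sum is smooth and
analytic, is cheap to evaluate at millions of points, and reproduces the
qualitative picture the benchmark needs: a 3 × 4 grid of twelve minima of
uneven depths. At thermal equilibrium, occupancy follows the Boltzmann
factor

$$p(c) \;\propto\; \exp(-E(c)/kT),$$

so deep wells are strongly occupied and the flat background is occupied in
proportion to $e^{-0} = 1$ per unit area. `occupancy_density()`
discretizes $p$ by the midpoint rule on a square lattice and normalizes
the cell masses to sum to one (asserted to $10^{-12}$).

### Default well table

```{r}
default_wells()
```

Three default choices deserve justification.

**Centers sit slightly off round coordinates.** Grid-commensurate centers
such as $c_1 = 0.125$ fall *exactly on the boundary* between two lattice
cells at any resolution divisible by 8, because cell midpoints are odd
multiples of $1/(2r)$. The two adjacent cells then carry identical density
to the last bit, and a "strict local maximum" (a cell greater than all 8
neighbors) is ill-defined — whole rows of wells vanish from the mode
count. The defaults (columns 0.13, 0.38, 0.63, 0.88; rows 0.17, 0.49,
0.83) keep the even 3 × 4 layout while letting each well peak strictly
inside one cell at all the lattice resolutions in routine use, so the
lattice density has exactly twelve strict maxima at resolution 64 and
above.

**Depths are 10–12.5 kT.** The benchmark's central fixed point is that an
ideal method — one that returns the true $(c_1, c_2)$ per particle — must
score 100 % balanced accuracy. That requires the equilibrium ensemble to
be *separable*: essentially every sample must lie in the basin whose label
it carries, and the per-well class means must coincide with the well
centers. With shallow wells (a few kT) over a flat background, a large
fraction of the Boltzmann mass sits in the featureless region *between*
wells (for 2–4.5 kT depths, over half); class means are dragged toward
basin centroids, nearest-mean boundaries shift, and even the perfect
embedding loses a few percent. At the default depths the background mass
fraction is about $3\times10^{-3}$ and its effect on the class means is
negligible, so samples form twelve clean clusters — the regime the
benchmark depicts — while the Gaussian tails keep the landscape
continuous. Barriers of 10–20 kT between long-lived conformational states
are physically reasonable for large molecular machines.

**Width 0.022.** At a column spacing of 0.25 the nearest basin boundary is
more than 5 standard deviations from each center, making the probability
that a well's own sample crosses into a neighboring basin
$\sim 10^{-8}$ per particle — invisible at the $10^4$–$10^5$ sample sizes
used here — while the tails still overlap smoothly.

$kT = 1$ throughout: the temperature never appears separately, so energies
are reported in kT units.

### Sampling

`sample_conformations()` uses rejection sampling: proposals uniform on the
domain, accepted with probability $w(c)/w_{\max}$ where
$w(c) = e^{-(E(c) - E_{\min})/kT}$. This is exact (no burn-in or
autocorrelation, unlike MCMC) at the cost of an acceptance rate equal to
the ratio of mean to peak Boltzmann weight — about $10^{-3}$ for the
default landscape. Sampling $10^5$ conformations costs roughly $10^8$
energy evaluations (under a minute); the generator is vectorized and sizes
proposal batches from the measured acceptance rate. $E_{\min}$ is taken
over the well centers and a $512^2$ lattice with a $10^{-6}$ safety
factor; for Gaussian wells separated by many widths the true minimum lies
at a well center to within $10^{-11}$, so the envelope is valid.

Ground-truth labels are the Voronoi rule: a conformation belongs to the
nearest well center (Euclidean), ties to the lowest id. This extends "the
snapshots of minimum $n$" to every point of the continuous domain with no
free parameter.

Determinism: every stochastic operation runs under an explicit seed with
the caller's RNG state saved and restored. Per-particle noise streams are
derived from (seed, index), so any particle's noise can be regenerated in
isolation and generation order is immaterial.

## The two-body phantom

The ribosome-like object is a Gaussian-blob mixture: a large subunit (LSU,
six blobs, lower half of the box) that never moves, and a small subunit
(SSU, four blobs, above it) that rotates rigidly about a pivot at the
interface — the ratchet-like motion characteristic of ribosomes. The two
rotation axes are orthonormal (x and y by default) and the conformational
coordinates map linearly onto angles,

$$\alpha = \alpha_{\max}(2c_1 - 1), \qquad
  \beta = \beta_{\max}(2c_2 - 1),$$

with $\alpha_{\max} = \beta_{\max} = 10^\circ$ by default, the magnitude
of real SSU ratcheting. Rotations compose as
$R(\text{axis}_2, \beta)\,R(\text{axis}_1, \alpha)$ (axis 1 first); at
$\le 10^\circ$ the commutator is second-order small, but the order is
fixed and documented rather than left to chance.

A blob model instead of an atomic-model map keeps everything closed-form:
rotation transforms blob *parameters* (no voxel resampling, so no
interpolation artifacts), the total analytic mass
$\sum_i a_i (2\pi)^{3/2}\sigma_i^3$ is exactly conformation-independent,
and a 3-D blob projects analytically to a 2-D Gaussian of the same sigma.
Volumes are rendered only for inspection and for oracle cross-checks; the
voxelized mass agrees with the analytic mass to better than 1 % at the
default 64-voxel box because every blob is kept at least 3σ inside the
box (enforced at construction).

Arrays are indexed with x fastest (R's column-major first index), matching
the MRC on-disk layout; the origin is the box center and angles are
counter-clockwise positive looking down each axis.

## Image formation

`project_particle()` forms the orthographic line integral along z after
orienting the blob set by a ZYZ Euler rotation (Relion-style rot, tilt,
psi), i.e. standard weak-phase cryo-EM image formation without the
microscope. Orientations in `generate_dataset()` are drawn uniformly over
SO(3) (rot and psi uniform on ±180°, tilt from the sin-density via
$\arccos$ of a uniform variate) or held at a single fixed view — the
fixed-view mode exists so image-space PCA has a meaningful input.

**Noise and SNR.** The benchmark condition is SNR = 1. SNR is defined as
pooled signal variance over noise variance across *whole frames* (no
particle mask): the noise-free stack is generated first, one global
$\sigma = \sqrt{\mathrm{Var}(\text{signal})/\mathrm{SNR}}$ is calibrated
from it, and i.i.d. zero-mean Gaussian noise is added per pixel. A single
global sigma keeps the noise stationary across conformations; the
whole-frame convention is the simplest one that is exactly reproducible.
With 500 or more particles the realized ratio
$\mathrm{Var(signal)}/\mathrm{Var(noise)}$ lands within a few percent of
target.

No CTF is applied by default — the benchmark condition states only the
SNR. An optional per-particle phase CTF
($-\sin(\pi\lambda\,\Delta z\, k^2)$, defocus drawn uniformly from a
configurable range and recorded in the metadata) can be switched on for
users who want microscope-like images; it is excluded from all
benchmark-defining checks.

Defaults of 64-px images at 3 Å/px are stand-ins chosen to resemble a
binned ribosome dataset; both are configurable. Full
$3\times10^6$-particle generation is supported by the same code path but
the package's own checks run at $10^2$–$10^5$ particles.

## The accuracy metric

Given any per-particle embedding (dimension $d \ge 1$; the benchmark
examines the top two coordinates of each method) and the ground-truth
labels, `evaluate_embedding()` applies exactly the nearest-center
procedure:

1. the center of each minimum is the *mean* of the embedding coordinates
   of the particles truly belonging to it;
2. squared-Euclidean distances to the 12 centers are computed;
3. each particle is binned to its nearest center (ties to the lowest id);
4. per-well recall is $\mathrm{Recall}(n) = \mathrm{TP}(n)/\mathrm{P}(n)$,
   and the balanced accuracy is the unweighted mean
   $\sum_n \mathrm{Recall}(n)/12$, reported in percent together with the
   standard deviation of the twelve recalls.

Recall is 1 when every snapshot of a minimum is correctly allocated and 0
when none is. The recall standard deviation uses the population
convention (divide by 12) by default — the sample convention is one
argument away — because the twelve wells are the entire population of
classes, not a sample from one. No normalization or whitening is applied
to the embedding: the metric is invariant under rotation, isotropic
scaling and translation of the embedding (means transform with the data
and squared distances scale uniformly), but *not* under anisotropic
scaling, which genuinely changes nearest-center boundaries — that
sensitivity is part of what the metric measures.

Degenerate inputs fail loudly: a well with no true members makes recall
undefined and raises an error naming the well, as does an empty class at
the center-computation step.

## Occupancy maps, energy inversion, lineage

`occupancy_map()` is a normalized 2-D histogram over the embedding range
(40 × 40 bins by default — coarse enough that well bins hold hundreds of
counts at $n = 10^5$, fine enough to resolve 12 wells).
`energy_from_occupancy()` inverts the Boltzmann relation,
$E = -kT\ln p$, shifted so the minimum is zero. Bins with fewer than
`floor_count` counts (default 1, i.e. empty bins) are masked `NA` rather
than extrapolated: inventing multi-kT energies for unvisited states from
zero counts would be pure artifact. On $10^5$ ground-truth samples the
inverted surface correlates with the generator energy at bin centers with
Pearson $r \approx 0.98$; the residual is binning (the bin integral of a
sharply varying density versus the center value) plus Poisson noise in
sparse bins.

`lineage_map()` colors each particle by its ground-truth minimum through
a fixed 12-color palette, so mixing and distortion in a method's output
space are visible directly; the output is a plain table plus an optional
PNG scatter.

One subtlety worth recording: for Gaussian wells, basin occupancy follows
the basin *free energy*, not the well-bottom energy alone — the
$e^{-E}$ peak of a well of depth $d$ has effective width
$w/\sqrt{d}$, so deepening a well also sharpens it and its mass grows as
$e^{d}/d$, not $e^{d}$. The package's two-state checks therefore scale
the deeper well's width by $\sqrt{d_1/d_2}$ when a clean
$e^{\Delta E}$ occupancy ratio is wanted; users building their own
landscapes should expect mass ratios between unequal wells to include
this entropic term.

## Reference embeddings and distortions

To exercise the scoring pipeline without any external heterogeneity
software the package ships the two ends of the quality spectrum plus
controlled degradations:

- `embed_oracle()` returns the true $(c_1, c_2)$ — the ideal method, and
  the fixed point of the benchmark: accuracy 100 %, recall spread 0 on
  the separable default landscape.
- `embed_pca()` is the simplest real estimator: PCA scores of the
  flattened, mean-centered images. It is deliberately restricted to
  fixed-orientation stacks — on mixed views image-space PCA conflates
  pose with conformation, which is precisely the hard problem the
  benchmarked tools exist to solve, so the restriction is enforced with
  an error instead of silently returning a meaningless embedding.
  Component signs are fixed by making each component's largest-magnitude
  loading positive, so scores are reproducible.
- `distort_embedding()` mimics observed failure modes: additive Gaussian
  noise (graded blurring of the landscape), random rotation with
  anisotropic scaling (the affine distortions linear methods produce),
  row shuffling (total loss of conformational signal — scores at the
  $100/12 \approx 8.3\,\%$ chance level), and collapse to one dimension
  (a method that finds only one of two motions: the three wells in each
  column become inseparable and accuracy drops to what the 1-D Voronoi
  partition of the column means can achieve).

Accuracy responds to these as a benchmark metric must: monotonically
non-increasing in expectation with noise magnitude, chance-level under
shuffling, strictly reduced by collapse.

## Numerical choices and problem sizes

- Tolerances: occupancy normalization $10^{-12}$; analytic-vs-brute-force
  oracle agreement $10^{-12}$ relative (means, recalls, energies) and
  $10^{-8}$ for eigendecompositions; mass conservation 1 % (voxel
  truncation at the box edge); projection-vs-ray-sum $10^{-3}$ of peak
  (midpoint integration along z).
- Tie-breaking is everywhere "lowest well id", stated once and used in
  both the ground-truth labeling and the metric's assignment step.
- The package's own statistical checks run at fixed seeds with
  $10^4$–$10^5$ samples and tolerances of 3–5 standard errors computed
  from the binomial or multinomial sampling distribution of the quantity
  under test, never from the observed spread alone.
- File formats: MRC2014 mode-2 float32 with correct dimension, cell and
  machine-stamp fields; Relion-dialect STAR with `_rln` orientation
  columns plus `_elb`-namespaced ground-truth columns; fixed float
  formatting so all writers are byte-deterministic.

## What the synthetic data does and does not show

The generator reproduces the *geometry* of the benchmark: a known
two-coordinate landscape, Boltzmann-weighted continuous conformations, a
rigid two-body motion, known uniform orientations, and stationary
Gaussian noise at a calibrated SNR. It deliberately omits much of what
makes real cryo-EM hard: CTF (off by default), structural/solvent noise,
ice gradients, beam-induced motion, orientation bias, flexible (non-rigid)
deformation, and pose *estimation* (ground-truth orientations are given,
as in the original benchmarking design). A method scoring 100 % here has
demonstrated only that it can recover a clean two-dimensional rigid-body
signal under white noise with known poses; failures here are strongly
diagnostic, successes are necessary but not sufficient for real data.

The per-well recall decomposition is also blind to *within-well*
distortion: any embedding that keeps the twelve basins separated scores
100 % even if distances within a basin are badly warped. The occupancy
and energy maps, and the lineage coloring, exist precisely to expose what
the scalar accuracy cannot.
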