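---
title: "Methods: 3D quantification of tau pathology in the locus coeruleus"
author: "lctau"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D quantification of tau pathology in the locus coeruleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`lctau` quantifies cellular tau pathology in volumetric two-channel scans of
the human locus coeruleus / pericoerulear (LC/PC) complex: the TH channel
(tyrosine hydroxylase) marks the reference population of noradrenergic
neurons, the AT8 channel marks hyperphosphorylated tau. The pipeline covers
five analysis stages:

1. **Soma detection** (`detect_cells`): background subtraction, global
   threshold, hole filling, size filtering, and watershed splitting of merged
   somas seeded by local maxima of the smoothed Euclidean distance transform.
2. **Body/process decomposition** (`split_body_process`): morphological
   opening with a Euclidean ball separates thick cell bodies from thin
   neurites, exploiting the scale gap between soma radii (roughly 9–15 um)
   and process radii (1–2 um axons, 3–4 um proximal dendrites).
3. **Regional and dorso-ventral quantification** (`regional_burden`,
   `split_dorsoventral`): AT8 volume and cell-count normalizations per
   subregion (core, shell, A4, subcoeruleus) and for the two equal-volume
   dorso-ventral halves of the core.
4. **Shell zoning** (`shell_zones`, `shell_profile`): concentric 100 um
   bands around cell bodies measure how far AT8+ processes reach from local
   somas.
5. **Spatial statistics** (`nni`, `cluster_analysis`): Monte-Carlo
   nearest-neighbour index, dense-cell detection, duo/minigroup components,
   neighbouring-cell analysis, and per-100-cell normalizations.

All geometry is computed in physical micrometres on anisotropic voxel grids
(`[z, y, x]` arrays; `(dz, dy, dx)` voxel sizes; point coordinates
`(x, y, z)` um with the origin at the centre of voxel `(0,0,0)`), so results
are invariant to resampling. The native scan sampling this emulates is
1.51 x 1.51 x 2 um; the phantom and tests default to 4–10 um isotropic grids
because every quantity of interest lives at the 10–100 um scale and the
coarser grids keep runs desk-scale.

## The nearest-neighbour index

For a pattern of $n$ cell centroids inside a region mask $W$, let
$\bar d_{obs}$ be the mean Euclidean nearest-neighbour distance. The null
model is complete spatial randomness (CSR) *inside the same mask*: each of
$S$ simulations draws $n$ uniform points in $W$ and records its mean NN
distance $\bar d_s$. The index is

$$\mathrm{NNI} = \frac{\bar d_{obs}}{\tfrac1S \sum_s \bar d_s},$$

with NNI < 1 indicating clustering and NNI > 1 dispersion. Two numerical
choices deserve note:

* **No analytic edge correction.** Because the null is simulated inside the
  same bounded mask, boundary effects cancel in the ratio; a Clark–Evans
  style correction would double-correct.
* **Denominator convention.** Averaging per-simulation means versus pooling
  all simulated distances are algebraically identical here because every
  simulation has exactly $n$ points; the package therefore does not expose a
  switch.

CSR sampling picks a foreground voxel uniformly and jitters uniformly within
it — exactly uniform over the digitized mask, with no rejection loop.
Calibration is part of the acceptance suite: across 50 CSR replicates
(n = 500, 100 simulations each) the mean NNI must lie in [0.98, 1.02].

## Dense cells, duos, minigroups, neighbouring cells

* A cell is **dense** when its NN distance is *strictly* below 75% of the
  pattern's mean NN distance ("closer than" is a strict comparison).
* Dense cells are linked when their pairwise distance is strictly below the
  dense threshold (the default link radius); connected components of size 2
  are **duos**, sizes 3–9 **minigroups**, and sizes above 9 are counted
  separately as large groups rather than folded into minigroups.
* A dense cell is **neighbouring** when its NN distance is less than *or
  equal to* the mean NN distance of the TH+ cells of the same scan
  (non-strict, matching the definition "equal or shorter").
* Counts are normalized per 100 AT8+ cells; a zero denominator yields a
  flagged `NA`, never a silent zero.

With the default link radius every dense cell has a dense partner within
range, so components of size 1 cannot occur; they are still counted (as
`singleton_count`) for custom link radii.

## The synthetic phantom: what it emulates, and what not

The study's raw scans are not deposited, so every stage is exercised on a
synthetic phantom (`make_phantom`) whose *stated world* is fixed up front:

* **Geometry** — a caudo-rostrally elongated cylindrical core (default
  radius 300 um, length 2.4 mm), an annular shell around its rostral third,
  a dorsomedial A4 band, and scattered ventrolateral subcoeruleus
  ellipsoids. Region geometry is deterministic (seed-independent).
* **Cytoarchitecture** — TH+ somas are placed by sequential-inhibition CSR
  (hard-core 32 um: somas do not interpenetrate) at region densities that
  put roughly 80% of cells in the core; a small fraction (default 3%) get a
  close "hugging" partner soma, the configuration the watershed must split.
  Somas are 15 x 9 x 9 um ellipsoids — an assumption, the source reports
  soma sizes only in supplementary material not reproduced here — oriented
  rostro-caudally in the core and dorso-ventrally in the subcoeruleus.
* **Pathology** — the AT8+ subset of TH+ cells (nesting holds by
  construction) has a stage-dependent fraction (defaults 0.02 / 0.05 /
  0.15 / 0.6 for Braak groups B0/B12/B34/B6 — free choices mirroring the
  qualitative stage trend, not measured claims), a dorsal bias (the dorsal
  AT8+ count is drawn binomially with the configured probability, then
  placed in the dorsal half), and within-half clustering: cluster seeds
  recruit their nearest TH+ neighbours, producing duos and minigroups among
  existing somas. The free-floating Thomas process (CSR parents, Gaussian
  offspring, offspring outside the mask resampled so n is exact) is exposed
  separately in `make_point_pattern` and drives the NNI acceptance target.
* **Morphology** — each AT8+ cell gets dendrite tubes (radius 3.5 um,
  random-walk polylines) and one thin axon (radius 1.5 um). The per-cell
  process voxel budget is `soma_voxels * (1/f - 1) * w`, where `f` is
  `body_fraction` (default 0.5, the core's ~1:1 body:process ratio) and
  `w` in {1, 0.6, 0.2, 0} encodes degeneration-form process completeness
  (intact pretangle, partial atrophy, severe atrophy, tangle-like). The
  *global* ground-truth body share therefore equals `f` only up to the mean
  form factor; with the default B12 form mix (E[w] ~ 0.9) it stays within
  0.05 of `f`. Severe and tangle forms carry no axon, matching the
  degeneration sequence in which dendritic trimming precedes the loss of
  all processes.
* **Intensity** — voxel intensity = background + amplitude x shape +
  Gaussian noise (defaults 200 / 2000 / 100 on a 16-bit scale);
  "low-intensity" somas are painted at 0.3x amplitude and "inhomogeneous"
  somas receive clipped log-normal multiplicative texture. These signatures
  are qualitative stand-ins — the source describes them only pictorially.

The phantom does **not** emulate: filamentous somatic protrusions,
disintegrating-cell debris, axonal varicosities, vascular structures, the
subependymal dendritic plexus, tissue autofluorescence gradients, or
light-sheet-specific stripe artifacts. A green recovery test therefore
establishes that the pipeline inverts the generator's forward model at
realistic SNR — not that it handles every real-tissue artifact.

## Numerical choices

* **Threshold default.** The spec'd Otsu default was replaced by a robust
  `median + k * MAD` threshold (k = 6 for soma detection, k = 4 for the AT8
  channel so that 0.3x-amplitude "low-intensity" somas survive). Otsu's
  between-class-variance criterion collapses into the noise distribution
  when the foreground occupies a tiny fraction of the volume (< 0.1%), which
  is the operating regime here; we verified this failure numerically. Otsu
  and fixed thresholds remain available.
* **Opening by Euclidean ball via distance transforms.** Erosion keeps
  voxels whose exact anisotropic squared distance to the background exceeds
  r^2 (strict); dilation takes voxels within r of the eroded set, clipped to
  the foreground. The strict/non-strict pairing makes the opening of a thick
  blob recover the blob while a tube of radius < r vanishes. The residual
  discretization bias (body volume underestimated by up to a one-voxel
  shell) is why body-share recovery is specified at +-0.1 at 4 um voxels.
* **Surface area** uses exposed-voxel-face counting: exact on the voxel
  grid, overestimates smooth surfaces (x1.5 for a sphere in the fine-voxel
  limit), consistent across cells — adequate for the ordinal comparisons it
  supports.
* **Branch counting**: topology-preserving 3D thinning (simple-point
  removal, endpoints retained), spur pruning below 2x the dendrite radius
  (default 7 um), then `n_branches = max(0, endpoints - 1)`; an isolated
  voxel has one "endpoint" and zero branches.
* **Watershed over-split suppression**: distance-transform maxima closer
  than 12 um are merged, deepest first, before seeding.
* **Dorso-ventral cut**: a single plane chosen by exhaustive scan to
  minimize the volume imbalance; ties give the extra slab to the dorsal
  side; the imbalance can never exceed one cut-plane slab. Dorsal = low y
  by convention (the source states no axis convention); configurable.
* **Shell zoning**: each process voxel is assigned to the shell of its
  *nearest* cell body — an exact partition, avoiding the double counting a
  union-of-spheres reading would produce; the inner edge defaults to 50 um
  because the reference band of the 100 um-wide zoning is 50–150 um,
  implying a soma-proximal 0–50 um band. Shells are restricted to the
  chosen subregion (the alternative — truncation at the block boundary
  only — is a one-argument change, `regions = NULL`).
* **Degenerate inputs**: an empty process mask yields a flagged zero
  profile, not an error; a zero-variance paired difference reports t = 0,
  p = 1 when identically zero and t = +-Inf, p = 0 otherwise; duplicate
  points get NN distance 0 and are flagged.
* **Classification cut-points** (`form_thresholds`) are inclusive on the
  process/soma ratio (a ratio just above `r_partial` is intact) and must be
  monotone; defaults 0.05 / 0.35 / 0.78 assume the generator's intact
  ratio near 1.
* **Statistics**: Type-II sums of squares for the two-way ANOVA and ANCOVA
  (each main effect adjusted for the other; the original analysis does not
  state its SS type); Tukey HSD post-hoc; classical paired t. Constant
  responses report F = 0, p = 1 rather than NaN.
* **Semiquantitative cut-points** (counts <= 10 "+", <= 100 "++", above
  "+++") are config-only stand-ins — the five-grade scale is defined
  verbally ("0" = absent, "0/+" = a single cell, then sparse / moderate /
  high density).

## Cell-to-region assignment

A cell belongs to the subregion containing its soma *centroid* (the
alternative — any-overlap membership — is not what the counting scripts of
this field usually do, and the source does not specify). Detected centroids
within half a voxel of a mask boundary can fall just outside; the pipeline
clamps such points by voxel membership before NNI computation.

## Known limitations

* The morphological opening at 5 um needs voxels of at most ~4 um to
  resolve the soma/process scale gap; at 10 um voxels the body share is
  biased low by the one-voxel erosion shell (the radius check errors out
  below one voxel).
* The TIFF codec is deliberately minimal (baseline, uncompressed, 16-bit
  grayscale); it is not a general TIFF reader.
* The phantom's AT8 clustering operates on the fixed TH+ soma lattice, so
  its attainable cluster tightness is bounded below by the hard-core
  separation — tighter than ~32 um clusters require the free Thomas mode.
* Group-level statistics on phantom cohorts test calibration (type-I
  error), not power against the study's real effect sizes, which depend on
  unpublished scan-level variance.
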