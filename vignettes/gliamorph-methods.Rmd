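---
title: "Quantifying microglial morphology and terminal engulfment in 3D confocal stacks"
author: "gliamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphology and terminal engulfment in 3D confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorph)
```

## The measurement problem

Microglia — the resident immune cells of the brain — survey their
surroundings with ramified processes, and their morphology changes with
activation state. In developmental feeding circuits, microglia also prune
axon terminals (for example AgRP terminals in the hypothalamus, labeled
with a synaptophysin reporter), and both their shape and their phagocytic
activity respond to perturbations such as maternal high-fat diet during
lactation. The measurements this package automates are the ones such a
study reports per animal and compares between groups:

* **Morphometry** of each Iba1-labeled cell in a region of interest:
  total process length, Sholl branching complexity, cell volume, and the
  convex-hull "territory" the cell surveys; plus cell density per ROI.
* **Terminal detection**: punctate boutons modeled as spots of a fixed
  physical diameter (0.8 µm), detected with a 3D Mexican-hat
  (Laplacian-of-Gaussian) filter and an automatic k-means threshold.
* **Interaction classification**: each detected spot is classified by its
  signed distance to the nearest microglial surface — *contact* within
  1 µm of the surface, *engulfed* within the 0.5 µm interior shell —
  together with CD68⁺ (lysosomal) volume inside each cell.
* **Group statistics**: per-animal means, mean ± SEM, two-sided unpaired
  t-tests at α = 0.05, percent change.

Because published stacks for this kind of study are rarely deposited, the
package ships a synthetic microscopy generator that grows branching glial
cells and plants terminals with known classes, so every stage can be
validated against exact ground truth.

## Coordinate conventions

All modules share one convention: axis order (z, y, x), 0-based voxel
indices, and the physical position of voxel (k, j, i) at its center,
$((k+0.5)\,d_z, (j+0.5)\,d_y, (i+0.5)\,d_x)$ µm. Voxel sizes are strictly
positive and may be anisotropic (confocal stacks are commonly sampled at
0.1 µm in z with a coarser lateral pixel size). A file without voxel-size
metadata is a hard error unless an explicit override is supplied: a wrong
default would silently corrupt every µm-scale quantity downstream.

## Segmentation and the exact 2-means threshold

The automatic threshold used throughout is a two-cluster k-means on
intensities. In one dimension the 2-means optimum is always a split of
the sorted values, so `kmeans_threshold()` computes it *exactly* by a
prefix-sum scan over all splits — no iterative heuristic, no random
restarts — and returns the midpoint of the two cluster means. Ties go to
the smaller split, making the result deterministic.

`segment_cells()` first smooths the channel with a small Gaussian
(default sd 0.4 µm, below the process radius). This matters more than it
looks: microglia occupy well under 1% of a stack's voxels, and on raw
data the two-means objective can be dominated by the noise distribution
of the empty background, placing the threshold inside the background
cluster. Smoothing collapses the background to a narrow peak and makes
the cell/background split the global optimum. Thresholding is followed
by 26-connected labeling and a minimum-volume filter (default 50 µm³,
well below a microglia but above noise blobs). The soma centroid is the
interior maximum of the Euclidean distance transform — the deepest point
of the mask — a standard proxy when no nuclear marker is segmented. On
stacks larger than half a million ROI voxels the threshold scan runs on
a deterministic stride subsample; the split point is unchanged at these
sample sizes.

## Skeletonization

The skeleton is extracted by geodesic path tracing in the TEASAR family,
rather than by voxel thinning. Mask voxels form a 26-connected graph
whose edge weights are physical step lengths multiplied by a centering
penalty $1 + c\,(1 - \mathrm{EDT}/\mathrm{EDT}_{max})^2$ (default
$c = 3$), so shortest paths run along tube centers. Process tips are
found by farthest-point search in geodesic distance from the soma; each
tip connects to the growing skeleton by its shortest path; the search
stops when every mask voxel lies within `coverage_scale` (default 2)
local tube radii of the skeleton. The result is a soma-rooted spatial
tree — acyclic *by construction* — and anisotropic voxels need no
resampling because all distances are physical.

We chose path tracing over topological thinning deliberately: sequential
simple-point thinning (including the widely used reference
implementations) can erode an even-width tube end-to-end — the remainder
stays topologically equivalent at every step, so nothing stops the
cascade — which destroys exactly the quantity we need (length).

Two post-processing steps control discretization artifacts:

* **Spur pruning** removes leaf branches shorter than `prune_length`
  (default 1 µm) — below any real process at this scale.
* **Chain smoothing**: voxel paths oscillate laterally by half a voxel,
  inflating arc length with spurious diagonal steps. Two Laplacian
  smoothing passes over degree-2 chain nodes (junctions, tips and the
  root stay fixed) remove the oscillation while leaving real curvature
  (radius ≫ one voxel) intact.

On a synthetic straight tube of 20 µm the measured skeleton length is
within 4% of truth; across full rendered cells the residual bias is a
few percent and multiplicative, so it cancels in group ratios.

`cell_morphometry()` reports `process_length` with the part of the
skeleton inside the soma ball (radius = mask depth at the soma centroid)
subtracted: the medial tree necessarily crosses the cell body, but the
cell body is not process. The raw edge-length sum is reported alongside
as `total_length`.

## Sholl analysis and territory

`sholl_profile()` counts, for each radius, the crossings of skeleton
edges with the sphere centered on the root — each edge treated as a line
segment, with the crossing count obtained exactly from the quadratic
along the segment (an edge that dips inside and out again counts twice).
The default radii step 1 µm from 1 µm to the maximal node distance. The
summary "branching complexity" is the sum of counts over all radii —
every process–sphere contact counts once — with the full profile always
returned so alternative summaries remain available.

Territory is the volume of the 3D convex hull of the skeleton nodes
(including the soma node), computed by an incremental hull with facet
visibility and horizon reconnection; the test suite checks it against an
independent brute-force facet-enumeration oracle to 1e-6 relative and
against exact polyhedra (tetrahedron 36 µm³, cube 1000 µm³). Degenerate
point sets (coplanar, collinear) raise explicit errors.

## Spot detection

`detect_spots()` follows the classical workflow: background subtraction
(a large-scale Gaussian estimate, default sd = 5 spot diameters,
computed on a mean-pooled pyramid for speed), Gaussian pre-filtering
(default sd = half the spot radius), then a scale-normalized 3D
Laplacian-of-Gaussian at $\sigma = r/\sqrt{3}$ — the blob-optimal scale
for a ball of radius $r$; the sigma is physical, so anisotropic voxels
are handled per axis. Candidates are 26-connected local maxima of the
response, with plateau ties resolved to the smallest voxel index
(determinism). The retained set is thresholded by `kmeans_threshold()`
over the candidate responses — thresholding detections, not billions of
background voxels, keeps the two clusters (noise maxima vs real spots)
well conditioned. Maxima within one spot radius of the stack border are
flagged and not retained, since truncated spots bias centroids; retained
centroids are refined by an intensity-weighted mean over the
spot-radius neighborhood. The default 0.8 µm diameter is the calibrated
terminal size; it is a configuration input.

At a peak signal-to-noise ratio of 10 (spot amplitude = 10 × read-noise
sd) with 50 non-overlapping spots per 19.2 µm stack, detection runs at
recall and precision above 0.95 (the acceptance suite measures both over
20 stacks).

## Signed distance and the engulfment rule

`signed_distance()` computes, at every voxel, the exact anisotropic
Euclidean distance (Felzenszwalb's exact transform, per axis) to the set
of cell-surface voxels, negative inside the mask, zero on the surface
voxels themselves, together with the nearest cell id. Spot centroids are
evaluated by trilinear interpolation.

The classification rule lives in one function used by both the
measurement path and the synthetic ground truth (`classify_distance()`):
with signed distance $d$ at the spot centroid,

* **engulfed** if $-0.5 < d \le 0$ µm (mode `"shell"`, the literal
  reading of "within 0.5 µm of the internal surface"), or $d \le 0$
  under mode `"full_interior"`;
* otherwise **contact** if $|d| \le 1$ µm — the rule is symmetric in
  sign, so a centroid just inside the surface that fails the engulfment
  test still counts as a contact rather than falling into a gap at
  $d = 0$;
* otherwise **free**.

The shell reading excludes deeply internalized spots, which is
biologically surprising; such spots are always flagged `deep_interior`,
and mode `"full_interior"` is provided, so both readings are reportable
from the same run. CD68 volume is quantified inside the union of cell
masks only, thresholded by the same exact 2-means over in-mask
intensities.

## The synthetic generator

`grow_glia()` grows a branching tree: `n_primary` processes leave the
soma in quasi-uniformly spread directions; segment lengths are Gamma
distributed (mean `mean_segment`, CV `segment_cv`); after each segment
the process branches into two with probability
$1 - e^{-\lambda L}$ (branch rate $\lambda$ per µm — branch points at
exponentially distributed arc-length intervals), up to `max_depth`;
`tortuosity` jitters directions. This law was chosen because its
expected branch count has a closed form, which the test suite checks by
Monte Carlo against an independent enumeration. The cell mask is the
union of the soma ball and capsules (tubes) around the segments; the
recorded true process length is the exact sum of segment lengths
(radial soma edges excluded).

`render_scene()` renders the microglia channel as the blurred
(separable-Gaussian PSF) cell mask times an intensity, the terminal
channel as Gaussian spots of the stated physical diameter at the planted
centroids, and applies Poisson photon noise followed by Gaussian read
noise — the standard fluorescence noise model. Planted spot classes come
from *exact* capsule geometry via the shared rule above. Planted signed
distances keep a margin (default 0.15 µm) away from every class
boundary — larger than the worst-case half-voxel-diagonal discretization
error at the validation voxel size (0.1 µm, half-diagonal 0.087 µm) — so
a planted class can never flip under voxelization; the acceptance suite
requires zero disagreement over 50 scenes.

What the generator does *not* emulate: vascular and autofluorescent
background, spectral bleed-through, depth-dependent attenuation,
motion, and real microglial morphological diversity. Passing tests
demonstrate that the measurement chain is correct and well calibrated on
data obeying its stated assumptions, not that segmentation or detection
would be unbiased on arbitrary real tissue.

`cohort_spec()` drives two-group cohorts with per-animal seeds derived
as `master_seed + 100003 × animal index`, so cohorts are bit-reproducible
and animals independent. `example_cohort_spec()` freezes the validation
study conditions:

* **morphometry**: one ramified cell per 72 µm stack at 0.5 µm voxels,
  two stacks per animal. The MHFD group is a pure spatial rescaling of
  NCD processes — mean segment × 1.87 with branch rate ÷ 1.87, leaving
  the branching law untouched — so the planted mean process-length
  ratio is exactly 1.87 (an 87% increase, the magnitude reported for
  diet-driven remodeling), with mild somatic hypertrophy. Scaling the
  segment length alone would also change the branching law, because
  branching is per unit length.
* **terminals**: a 61% density increase (ratio 1.61) around a baseline
  of 15 terminals per 1000 µm³ at 0.2 µm voxels.
* **engulfment**: 30% planted engulfed, 20% planted contacts around a
  compact cell.

The problem sizes used by the validation suite — 20 animals per group,
two stacks per animal for morphometry, 20 detection stacks, 50
classification scenes, 1000 null comparisons, 200 power replicates — are
the package's chosen desk-scale study design; effect recovery is
asserted within ±15% of the planted ratios, and the planted 87% effect
is detected at p < 0.05 in over 95% of simulated cohorts (the power and
calibration replicates run on generator ground truth through the same
per-animal statistics, which is what makes 1000-fold replication
feasible).

## Statistics

The animal is the statistical unit everywhere: `aggregate_per_animal()`
averages cells/spots within animal first, so group means are means of
animal means, never pooled-cell means (the tests pin this on an
unbalanced fixture). `unpaired_t_test()` defaults to the Student
(pooled-variance) variant — matching the common Prism default behind
plain "unpaired t-tests" — with Welch available by flag; two-sided,
significance at α = 0.05, percent change relative to the reference
group. No multiple-testing correction is applied, by design fidelity;
the report footer states this. Reports are written with fixed ordering
and fixed float formatting, so regeneration from the same tables is
byte-identical, and every table carries the MD5 hash of the resolved
configuration (output paths excluded, so the hash identifies the
analysis, not the directory it ran in).

A worked end-to-end example:

```{r example, eval = FALSE}
cfg <- list(
  mode = "simulate", seed = 1, out_dir = "run",
  cohort = example_cohort_spec("morphometry", animals_per_group = 4))
res <- run_pipeline(cfg)
subset(res$report, metric == "process_length")
```

## Numerical choices and degenerate inputs

* Exact EDT uses a large finite sentinel instead of IEEE infinity, which
  keeps the lower-envelope recursion well defined on empty rows.
* The 2-means threshold errors on all-identical values ("degenerate
  distribution"); segmentation interprets that as "nothing to segment".
* An all-zero terminal channel yields zero spots; a single candidate is
  retained without thresholding (one observation cannot be split).
* Convex hulls of < 4 points, collinear or coplanar sets raise explicit
  degeneracy errors; cells whose skeleton collapses to a near-point get
  `NA` territory rather than a fabricated value.
* Zero retained spots make the engulfed fraction `NA` with a warning,
  never 0.
* t-tests with zero variance in both groups error; report generation
  skips such degenerate metrics instead of aborting the run.
* Plateau local maxima, component labeling order, ROI tie-breaks (a
  point on a voxel boundary belongs to the higher-index voxel) and seed
  derivations are all fixed, so every pipeline stage is a pure function
  of (inputs, config, seed).

## Limitations

Segmentation is a global threshold: touching cells merge into one
component, so the density metric counts somata but per-cell morphometry
assumes non-touching cells (the generator places cells apart
accordingly). Skeleton length carries a small multiplicative
discretization bias (a few percent at 0.5 µm voxels) that cancels in
group ratios but not in absolute values. The spot model is a fixed
single diameter; closely apposed terminals below the resolution merge.
The CLI (`inst/cli/gliamorph.R`) is a thin wrapper; programmatic use via
`run_pipeline()` is the primary interface.
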