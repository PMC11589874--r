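---
title: "From tilted scanner scenes to single-tree point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tilted scanner scenes to single-tree point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A permanent laser scanning (PLS) station — a terrestrial LiDAR mounted high
on a mast and tilted down at a fixed forest scene — produces dense point
clouds of the same trees, scan after scan, for months or years. Turning those
raw full-scene clouds into *per-tree* point-cloud time series requires a
chain of geometric and segmentation steps: levelling the tilted scanner
frame, georeferencing, detecting stems, cutting per-tree buffers,
normalizing heights against a terrain model, delineating each crown point by
point, and cataloguing the result with per-tree metadata and quality flags.
`plstree` implements that chain end to end, together with a synthetic scene
generator that emulates the acquisition geometry so that every stage can be
validated against known ground truth without field data.

This vignette explains each stage's model and assumptions, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
scenes do and do not demonstrate about real data.

# Coordinate frames and rectification

The scanner delivers points in its own tilted frame with the instrument at
the origin. `rectify()` applies the passive Euler rotation
`R = Rz(kappa) Ry(phi) Rx(omega)` (degrees, right-handed axis rotations);
for a mast-mounted instrument tilted 60 degrees down the pose is
`(0, 60, 90)`, which leaves a right-handed frame with Z up, origin still at
the instrument, and the ground near `z = -(mast height)`. The composition
order is a package convention — validated by the physical constraint that
the default pose turns the tilted boresight scene ground-horizontal — since
angle names alone do not fix an order. Scan angles (`theta` from +Z,
`phi_az` from +X towards +Y) and range are derived by
`computeScanAttributes()` in the *pre-rectification* scanner frame, because
they describe instrument geometry; ranges are rotation-invariant either way.

# Helmert georeferencing

`fitHelmert()` estimates the 7-parameter similarity transform
`p' = t + mu * R p` from control-point pairs by minimizing the summed squared
target residuals. The solver is closed-form (centroid alignment, SVD
orthogonal-Procrustes rotation with a determinant correction, trace scale)
rather than an iterative linearization: for this loss the closed form attains
the global optimum, needs no initialization, and recovers noise-free
parameters to machine precision (~1e-12, asserted at 1e-9 in the tests).
Collinear control configurations are rejected (the second singular value of
the cross-covariance vanishes). `fitRMSE` is the 3-D residual RMSE
`sqrt(mean(||r||^2))`; per-axis RMSEs accompany it. Under isotropic Gaussian
noise of SD `sigma` on 8 points this statistic concentrates around
`sqrt(3) * sigma` with the fit absorbing 7 degrees of freedom, comfortably
inside the `[0.5, 2] * sigma` band the tests assert over 100 replicates.
Rotation angles are reported as pitch/roll/yaw under the same `Rz Ry Rx`
convention; at gimbal lock (`|phi| = 90` degrees) yaw is reported as 0 by
convention and the reconstruction remains exact.

# Noise filtering and voxel resampling

`filterNoise()` keeps points with `reflectance >= reflectanceMin` and
`deviation <= deviationMax`, both inclusive. There are *no* numeric
defaults: the appropriate thresholds depend on the instrument's radiometric
calibration and the site's atmosphere, so unset thresholds impose no
constraint and setting one while the attribute column is absent is an error,
never a silent no-op.

`voxelResample()` thins a cloud to one point per occupied cubic voxel
(default edge 0.05 m — the largest size still giving results comparable to
full resolution; larger voxels warn). Design choices:

* Voxel index is `floor((coord - origin) / size)` with half-open cells;
  the origin defaults to the floor of the cloud minima. This makes the
  partition deterministic and index arithmetic exact.
* The retained point is the *input point* nearest the centroid of the
  points in its voxel (the centroid of the occupants, not the geometric cell
  centre); no synthetic coordinates are ever created, so resampling is
  idempotent at a fixed size and origin, and every output coordinate exists
  in the input.
* Ties in the centroid distance go to the lowest input index, for
  reproducibility.
* The retained point carries per-voxel arithmetic means of `intensity`,
  `reflectance` and `deviation` (so `mean * count` conserves the input sums
  exactly), while identity-like fields (`return_number`, `label`) keep the
  retained point's own values.

The output count is property-tested against an independent hash-of-voxel-
indices oracle, and the implementation is vectorized grouping (data.table),
processing 1e6 points in about a second.

# Stem detection

`classifyStemPoints()` computes a PCA of each point's spherical
neighbourhood (radius 0.5 m by default — deliberately large, matching the
sparser-than-TLS point spacing of a long-range mast scan). A point is a stem
candidate when the neighbourhood holds at least 5 points, the eigenvalue
linearity `(l1 - l2)/l1` is at least 0.6, and the dominant eigenvector lies
within 15 degrees of the local terrain normal (a plane fit to the DTM
support near the footprint; flat terrain gives +Z). Ground returns fail the
linearity gate (two comparable eigenvalues), crown volumes fail both gates.

`clusterStems()` groups candidates by planimetric connectivity (link
distance 0.5 m), fits a cylinder to each group of at least 50 points, merges
groups whose axes hit the ground within the link distance of each other and
refits (this restores the coupling between clustering and model
reconstruction), intersects each axis with the DTM for the ground position,
and discards stems beyond 200 m (3-D) from the scanner — the reliable
detection limit of the emulated acquisition.

Three structural gates make the cluster-to-stem decision explicit, each a
config parameter:

* the cylinder is fitted on the cluster's lowest vertically contiguous
  segment (0.5 m occupancy bins), because the stem model describes the
  ground-rooted part — without this, line-like conifer tops merged into the
  cluster by planimetric connectivity tilt the axis and displace the ground
  position by up to a metre;
* fitted axes tilted more than `maxAxisTilt` (default 5 degrees) from plumb
  are rejected: measured on synthetic scenes, genuine stems fit within 0.3
  degrees while crown-edge silhouettes follow the crown slope at 9 degrees
  and more, so the gate sits in a wide empty margin;
* fitted radii above `maxStemRadius` (default 0.5 m) are rejected (planar
  crown sheets fit with arbitrary large radii), and clusters whose lowest
  point floats more than `maxBaseHeight` (default 8 m) above local ground
  are not rooted and are dropped.

`fitCylinder()` itself minimizes `sum((dist_i - r)^2)` over axis point (2
degrees of freedom in the plane perpendicular to the initial direction),
axis direction (2 dof) and radius with Levenberg–Marquardt, initialized from
the neighbourhood PCA direction and an algebraic (Kasa) circle fit of the
projected points. The translation along the axis is a flat direction of the
objective; LM's damping handles the rank deficiency without special-casing.
Noise-free cylinders are recovered to well below 1e-6; the radius estimator
is consistent (error decreasing with noise) by property test.

`coarseSegment()` then cuts, per stem, the boundary-inclusive 3.5 m
planimetric cylinder buffer over the full height extent; overlapping buffers
intentionally duplicate shared points, since fine segmentation re-decides
ownership per buffer. Buffers are not clipped vertically (the method needs
the crown top for seeding).

# Height normalization

`normalizeHeights()` subtracts the ground elevation of the nearest DTM
support point from each point's z, leaving x and y untouched, so the
operation is exactly invertible with the same DTM (`denormalizeHeights()`).
Nearest-support lookup (rather than interpolation) keeps the operation
invertible and exact on gridded DTMs; with the default 20 cm DTM resolution
the approximation error is below the ground roughness it feeds into. Points
farther than five DTM resolutions from any support indicate non-overlapping
footprints and raise an error with the offending count.

# Fine segmentation: layers, DBSCAN, fuzzy k-NN

The buffer is sliced into 0.5 m horizontal layers (`[j t, (j+1) t)`,
half-open so every point belongs to exactly one layer). Each layer is
clustered with DBSCAN in the horizontal plane only (eps 0.4 m, core
threshold 5, neighbourhood counting the point itself). The implementation is
deterministic — expansion starts at the lowest-index unvisited core point
and border points join the first cluster that reaches them — and is verified
in the tests against an independent brute-force reachability oracle.

`detectTrees()` stacks the per-layer cluster centroids, links them
planimetrically (0.5 m tolerance), and accepts a stack as a tree when it
spans at least 4 distinct layers and its least-squares 3-D line is within 15
degrees of vertical; the apex is the topmost layer's centroid (the local z
maximum), and tree ids are assigned in decreasing apex height. Single-layer
understory blobs never seed a tree.

`segmentLayers()` sweeps the layers bottom-up by default (stems anchor tree
identity near the ground, where trees are most separated; top-down is
available). Every unlabelled point takes the argmax fuzzy k-NN membership
(`k = 10`, fuzzifier `m = 2`, weights `d^(-2/(m-1))`, coincident points get
full membership) computed against *all* points labelled so far — seeds,
previous layers, and already-processed points of the current layer in
ascending index order. This maximizes the labelled evidence available to
each decision; the alternative (previous layer only) discards the seeds'
vertical context and was not pursued. A point whose nearest labelled
neighbour is farther than 1.5 m stays unassigned (label 0) rather than being
force-assigned — mirroring how unsalvageable points are excluded from
published per-tree products. Distances are 3-D. The sweep is deterministic
for a fixed configuration, and bit-exact across repeat runs.

Points below `groundHeightMin` (0.3 m normalized height) are treated as
ground: excluded from seeding and left unassigned. A buffer is centred on
its stem, so the ground disc's planimetric centroid coincides with the stem
position and would otherwise be absorbed into the tree, wrecking both the
label accuracy and the per-tree densities. The residual cost is that true
stem returns below 0.3 m stay unlabelled — a fraction of a percent of a
tree's points.

All the fine-segmentation defaults are package choices exposed in
`layerSegConfig()`; appropriate values depend on point density and crown
geometry, and published parameterizations for comparable data are not
available (the original values were grid-searched and not reported).

# Per-tree attributes, quality and the catalogue

Tree height is the 99.95th percentile of the z coordinates (linear
interpolation between order statistics — the standard `quantile` type 7
rule; a 1001-point ladder from 0 to 10 m gives exactly 9.995 m) minus the
ground elevation at the nearest DTM support to the tree location, which is
the stem ground position (not the cloud centroid, which shifts with crown
asymmetry). Scanner distances are plain 3-D distances to the highest
retained point and to the stem base. Point density is the count over the
area of the planimetric convex hull — the footprint definition is a package
choice, stated here because "per square metre" alone does not define an
area; degenerate hulls (fewer than three non-collinear points) report a
missing density rather than a fabricated one.

The completeness quality level is a total mapping from commission (foreign
points included) and omission (tree structure missing): failed segmentation
is 0, neither flaw 4, commission only 3, omission only 2, both 1. On
synthetic scenes `scoreCompleteness()` computes the flags automatically
against truth labels with tolerances of 5% (commission) and 10% (omission);
at tolerance zero the scoring reduces to strict set equality. On real data
the flags come from expert inspection; the pipeline accepts that pathway by
scoring only when truth labels exist and otherwise flagging successful
segmentations as level 4 and failures as level 0.

Scan selection applies strict bounds: wind below 3 m/s, relative humidity
below 90%, no precipitation, no snow — a scan at exactly 3 m/s or 90% is
rejected. File names follow `YYMMDD_HHMMSS_treeID_Quality.laz` with
unpadded tree ids; `parseTreeFilename()` inverts `makeTreeFilename()`
exactly. The JSON catalogue is a GeoJSON-style feature collection with fixed
key order, so identical records serialize byte-identically — the property
that makes pipeline re-runs verifiable by file comparison.

# The synthetic scene generator

`generateScene()` emulates the acquisition: a scanner 30 m above ground,
tilted 60 degrees down, 87 x 151 degree field of view, casting an angular
ray grid against analytic primitives — a bounded (possibly sloped) ground
plane, vertical stem cylinders, cone crowns for conifers, ellipsoid crowns
for birch. With occlusion on, only the first intersection per ray survives,
so stems show only their scanner-facing side and trees can shadow each
other, reproducing the single-view character of the real data. Gaussian
range noise (SD 5 mm, the instrument's nominal accuracy) perturbs hit
distances; crown interiors receive volume-sampled foliage points at 30% of
the visible shell count (a fully occluded crown therefore receives none);
uniform frustum outliers (0.1%) and class-dependent reflectance/deviation
distributions give the noise filters something real to do. Scenes are fully
determined by the seed.

Default study conditions: 10 trees, pine/spruce/birch mixed 3/1/1 (the
species balance of the emulated stand), at least 2 m spacing by rejection
sampling, in a 40 m x 40 m plot centred 45 m in front of the scanner — far
enough that crowns are seen obliquely from above, close enough that stems
are resolved at the test angular resolution. That resolution is 0.05
degrees: the field instrument scans at 0.006 degrees, but that grid implies
on the order of 1e8 rays per scene, far beyond what a test suite should
spend; all geometric relationships scale with the grid, and the count-vs-
resolution law is itself property-tested. Problem sizes used by the checks:
the default scene casts ~650k rays yielding ~530k returns; the two-tree
buffer holds ~260k points; resampling is timed at 1e6 points.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: multiple returns per pulse and waveform effects,
wind-induced motion between or within scans, snow loading, phenological leaf
change, understory vegetation, radiometric realism of reflectance beyond
class-level separation, and branch-level crown structure. Results on
synthetic scenes bound the pipeline's geometric correctness, not its
ecological fidelity.

A note on visibility: under first-hit occlusion a tree can be entirely
hidden behind a nearer crown. Detection recall is therefore defined over
*visible* trees (`visibleTrees()`): those with at least `minClusterPoints`
ground-rooted stem returns, i.e. stem-class returns within `maxBaseHeight`
of their local ground — matching how published per-tree datasets exclude
trees absent from the data. A tree whose only stem returns are isolated
leader hits at its top is not detectable as a stem and does not count. Similarly, crowns taller than the upper edge of the vertical field of
view are clipped exactly as a real instrument would clip them, so height
estimates for such trees are honest underestimates of the planted truth.

# The pipeline and its guarantees

`runPipeline()` chains simulation (optional), scan-attribute derivation,
rectification, georeferencing (fitting the Helmert transform to the
control-point pairs), optional resampling (off by default — per-tree
products are published at full resolution), stem detection, coarse
segmentation, normalization, fine segmentation, attribute extraction,
quality flagging, and the catalogue. Each run writes a manifest with the
configuration hash, per-stage point counts (buffer totals equal assigned
plus unassigned, exactly), and the fitted transform. All stochastic stages
derive from the single seed, so a re-run with unchanged inputs reproduces
the catalogue byte for byte. Errors halt the run with the stage name; a
`FAILED` marker file retains the context.

A worked example:

```{r, eval = FALSE}
library(plstree)
cfg <- pipelineConfig(simulate = sceneConfig(seed = 42), seed = 42)
res <- runPipeline(cfg, "run42")
res$records[, c("tree_id", "species_index", "height_m", "quality")]
```

# Known limitations

* LAS input/output is uncompressed; LAZ requires a laszip codec and is
  detected and rejected with a clear message rather than misread. Files the
  package writes are always genuine LAS regardless of extension.
* The DTM reader accepts LAS point files and plain-text XYZ tables;
  georeferenced raster formats are out of scope.
* Single-scan scope: cross-scan tree identity comes from stem positions
  upstream, and no temporal label tracking is performed.
* Quality flags without ground truth collapse to a success/failure
  dichotomy (4 or 0); graded commission/omission levels need either truth
  labels or expert input.
* The stem detector assumes near-plumb stems (configurable tilt gate);
  strongly leaning trees would need a larger `maxAxisTilt` and would then
  reduce the safety margin against crown-silhouette false positives.
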