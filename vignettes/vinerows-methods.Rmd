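---
title: "Methods: vineyard point-cloud phenotyping with vinerows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vineyard point-cloud phenotyping with vinerows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinerows)
```

`vinerows` turns a georeferenced UAV point cloud of a vineyard into
per-row and per-plant phenotypes. This vignette describes the models and
procedures behind each stage, the parameters that matter, the design
choices that were genuinely open, and the limits of what the synthetic
test bed can show.

## Pipeline overview

The workflow has three parts, each usable on its own:

1. **Ground/plant separation and height normalization.** A
   cloth-simulation filter (CSF) splits the cloud into a terrain
   partition (`GroundPCl`) and a vegetation partition (`PlantPCl`); a
   raster terrain model built from the ground points converts absolute
   elevations into heights above ground.
2. **Row segmentation.** The plant cloud is voxel-downsampled, clustered
   in the horizontal plane with DBSCAN, aligned with the y-axis using a
   total-least-squares estimate of the row orientation, repaired by
   centroid merging, and the labels are propagated back to full
   resolution. Ground points inherit the segmentation through per-row 3D
   bounding boxes.
3. **Row parameter extraction.** Per segmented ground row, trunk
   positions are detected from local covariance sphericity; per plant
   row, canopy height, width, alpha-shape volume and lower bound are
   profiled in equal-length segments along the row.

## Ground separation (CSF)

The cloud is inverted in z and a particle grid of spacing `gr` (default
0.3 m) is draped onto the inverted surface: particles fall under gravity
(0.12 m per step, velocity damped at 1%), collide with the highest
inverted point of their cell and become pinned, and `rigidness` (default
2) smoothing passes per step pull each movable particle halfway toward
the mean of its four neighbours, which lets the cloth bridge vegetation
while following terrain. Iteration stops when the largest displacement
falls below 1e-4 m or after `iterations` (default 500) steps. A point is
ground when its vertical distance to the settled cloth is at most `dt`
(default 0.3 m).

Two consequences are worth knowing. First, trunk bases below `dt` end up
in the ground partition -- this is not a flaw but the signal trunk
detection relies on. Second, the method is insensitive to slope because
the cloth follows the pinned terrain particles; the test suite checks
that classification accuracy on a 10 degree slope matches flat terrain
within one percentage point.

There is no bit-compatible reference for this stage, so acceptance is
behavioral: on generated scenes with known labels, at least 99% of ground
and canopy points must be classified correctly.

The terrain model rasterizes ground points at `cell_size` (default
0.3 m, the cloth resolution). Each cell's elevation is the 5th percentile
of its member points -- low enough to resist residual vegetation
mislabeled as ground, high enough not to chase noise minima. Empty cells
fill from their neighbours, and queries interpolate bilinearly between
cell centers; how the ground elevation under a plant point is obtained is
not prescribed by the method's sources, so bilinear interpolation is the
documented default (nearest-neighbour behaviour falls out of the fill
rule for isolated cells).

## Row segmentation

Clustering runs on the 0.1 m-downsampled plant cloud projected to the
xy-plane, with DBSCAN at `eps` = 0.35 m and `min_points` = 40. Both
values follow the published calibration for vineyard-scale UAV clouds;
40 neighbours inside 0.35 m is comfortably exceeded inside a canopy strip
and essentially never met by stray returns.

Per-cluster directions come from the principal axis of the cluster's 2D
covariance. Row directions are axial (a row has no head), so per-cluster
angles are combined on the doubled angle, weighted by cluster size; the
result is the rotation that maps the common row direction onto the
y-axis, constrained to (-pi/2, pi/2]. The rotation pivot is the cloud's
horizontal centroid -- the pivot and angle are kept on the outputs so
every reported position can be mapped back to the original georeferenced
frame.

After rotation, clusters whose centroids differ by less than `d` = 1 m in
|dx| are single-linkage merged into one row: canopy gaps and separately
clustered posts produce fragments at the same cross-row position, while
adjacent rows sit a full row spacing apart. Only the cross-row coordinate
enters the merge rule. Rows are numbered by ascending mean x.

Full-resolution points inherit the label of their voxel representative.
Representatives that ended up as DBSCAN noise leave their points
unlabeled at first; those points then join the nearest row within
2 x `eps`, where a row is understood as its set of already-assigned
points and attachment is iterated to a fixpoint. The iteration matters:
a low-density canopy fragment whose representatives all fell below the
core threshold chains onto its row through its own contiguous points,
instead of depending on a single long hop to a downsampled
representative.

Ground rows are cropped with closed 3D boxes taking each row's rotated
x/y extents and the z extent of the whole ground cloud.

## Trunk detection

Ground rows are downsampled at 0.05 m and, for every point, the
covariance of all neighbours within `radius` R = 0.25 m (the scale of a
trunk plus surrounding ground) is eigendecomposed with eigenvalues
lambda1 >= lambda2 >= lambda3 >= 0. The sphericity S = lambda3 / lambda1
is ~0 on the near-planar ground and rises where a trunk cylinder adds
genuinely 3D spread. The neighbourhood includes the query point and the
covariance uses the 1/n normalization; any consistent choice leaves S
unchanged. Points with fewer than 3 neighbours get S = 0, which biases
them away from candidacy -- safe, because real trunks are locally dense.

The candidate threshold is computed per ground row by Otsu's method on a
256-bin histogram over the observed sphericity range (the bin count is a
convention; results are insensitive between 128 and 1024 bins). Ties
break toward the lower threshold. Candidates are clustered in 3D by
DBSCAN at eps 0.10 m / min_points 5 and each cluster's arithmetic
centroid is one trunk, reported in original coordinates.

Two caveats. Otsu always finds a split, so a trunk-free but noisy row
yields spurious candidates; in scenes where rows without any trunk-like
object are plausible, the detections should be screened by cluster size
or sphericity magnitude (the per-trunk CSV reports both). Metal posts are
geometrically trunk-like and are deliberately not discriminated; they
surface as false positives in the evaluation, consistent with how the
method is scored.

## Canopy parameters

Each rotated, height-normalized row is split into equal-length half-open
segments along y (250 segments by default, i.e. 10 cm on a 25 m row).
Per segment:

* **Height** is the mean of the heights at or above the segment's 90th
  percentile ("mean of the top decile"). The phrase "within the 90th
  percentile" admits two readings; the top-decile mean matches the
  90th-percentile crop-height practice this estimator descends from, and
  is the implemented default (the percentiles are configurable).
* **Width** is the mean of the cross-row coordinates in the top decile
  minus the mean in the bottom decile. The method's sources describe
  width as perpendicular to the row axis yet phrase the computation in
  terms of along-row values; since rows lie along y after rotation, the
  cross-row (x) reading is implemented and the literal along-row reading
  is available via `canopy_params(width_axis = "along")`.
* **Volume** is the 3D alpha-shape volume at alpha = 0.3 m: the Delaunay
  tetrahedra with circumradius <= alpha, summed. 0.3 m follows the
  canopy's concavity scale -- small enough to carve real indentations,
  large enough not to fragment the shape.
* **Lower bound** is the bottom-decile mean of the heights.

Volume and lower bound are computed on the SOR-filtered row (k = 10
neighbours, multiplier 2.0): sparse trunk and branch remnants below the
canopy would otherwise drag the lower bound toward zero and tether the
alpha shape to the ground. The SOR parameters are not prescribed
anywhere; k = 10 / 2.0 are the conventional defaults and are configurable.
Height and width use the unfiltered segments. Empty segments carry `NA`,
so gaps render as interruptions rather than fabricated zeros. Row totals
of volume are additionally reported at 1 m segmentation, where the alpha
shape is better conditioned than on 10 cm slivers.

## Numerical choices

* Voxel membership is `floor(coordinate / edge)`; boundary ties go to the
  lower voxel. The voxel representative is the centroid of its member
  points (not the voxel center), which preserves surface geometry for the
  covariance features.
* Percentiles interpolate linearly between order statistics
  (`stats::quantile` type 7).
* The Delaunay tetrahedralization behind the alpha shape is built
  incrementally (Bowyer-Watson) on a centered, deterministically jittered
  (1e-10 of the extent) copy of the coordinates to sidestep exact
  degeneracies; volumes and circumradii are evaluated on the original
  coordinates, so closed-form cases (a single tetrahedron) are exact and
  requesting several alphas from one call guarantees monotonicity by
  construction. Coplanar inputs return volume 0 with a warning.
* All internal computation runs in a local metric frame: readers split a
  UTM-scale offset into the cloud's `origin`, which writers and reported
  trunk positions add back.
* Reported percentages round half away from zero, the convention of
  published evaluation tables.

## The synthetic test bed

`generate_vineyard()` builds scenes with full ground truth: a planar
sloped terrain sampled on a jittered grid (100 points/m^2), 3-10 parallel
rows at a global bearing, plants at 1.0 +/- 0.15 m ("irregular vine
spacing"), trunk cylinders (radius 0.05 m, height 0.4 m, 60 surface
samples) under volumetric uniform canopy boxes (250 points/m^3), optional
posts, and isotropic Gaussian noise (sd 0.01 m; 1 cm is a typical
photogrammetric registration error at vineyard scale). The default scene
-- 7 rows of 25 m at 2 m spacing, bearing 20 degrees, slope 5 degrees,
three SMPH rows and four VSP rows -- mirrors the layout this pipeline was
designed around. A `density_scale` of 10 with noise sd 0.02 m emulates a
denser LiDAR survey.

The two canopy presets encode the training-system contrast: SMPH
(semi-minimal pruned hedge) at height 1.7 m, width 0.7 m, lower bound
0.5 m, near-continuous foliage; VSP (vertical shoot positioning) at
1.6 m, 0.35 m, 0.7 m, sparser foliage with more visible trunk. SMPH
strictly dominates VSP in height, width and cross-section, and an
`occlusion` factor couples trunk-point dropout to canopy density, so
detection recall degrades faster in SMPH rows when dropout is enabled --
the mechanism believed to drive the training-system differences seen on
real data.

Defects are modeled deliberately: a *missing plant* removes trunk and
canopy; a *canopy gap* carves an opening of 0.4-0.9 m symmetrically
across the boundary between two plants, so trunks always keep foliage
overhead and no detached canopy island can form. Defects are interior to
the row and separated by at least two intact plants; without that
spacing, independent defects compound into multi-meter openings and
orphaned sub-threshold fragments -- a degenerate regime outside the
continuous-row conditions the scene is meant to emulate (the limit case
`missing_prob = 1` bypasses the spacing rule and produces bare terrain).

What the generator does **not** emulate: the shell-like point
distribution of photogrammetric surfaces (canopy is volumetric uniform,
which is the simpler superset and makes the percentile estimators
analytically checkable), occlusion shadows and reconstruction artifacts
beyond random dropout, curved rows, understory vegetation, wind
deformation, and radiometry of any kind. Passing tests therefore show
that the algorithms are implemented correctly and behave as designed
under realistic geometry and noise -- not that the published real-data
scores transfer to any particular survey.

## Problem sizes

The default scene is ~75k points and runs the full pipeline in a few
seconds; the test suite uses a 3-row, 8 m variant for unit tests and the
full 7-row scene (10 seeds, both camera- and LiDAR-style densities) for
the end-to-end checks. The alpha-shape oracle checks run up to 20,000
points; the DBSCAN/Otsu/SOR brute-force equivalences use up to 300, 2,000
and 500 points respectively, sizes where the naive oracles are exact and
fast.

## Known limitations

* Rows are assumed linear; curved rows break the single-angle rotation.
* The cloth filter assumes the lowest surface is terrain; dense ground
  cover or terraces with overhangs will misclassify.
* Otsu thresholding presumes each ground row contains trunk-like
  structure (see above).
* Canopy width is meaningless in segments where the canopy is absent;
  consumers should treat `NA` as "no canopy", not zero.
* LAZ (compressed LAS) is not read; decompress externally first.
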