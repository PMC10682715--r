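# vinerows

Per-plant and per-row phenotyping of vineyards from UAV point clouds.

Vineyard managers and grapevine breeders need canopy height, width and
volume along every row -- and the position of every single vine -- to
steer spraying, pruning, defoliation and yield decisions. Manual
measurements sample a few spots and extrapolate; a georeferenced 3D point
cloud from a UAV survey (photogrammetric or LiDAR) covers the whole plot.
`vinerows` turns such a cloud into those phenotypes using geometry only:
no color, no assumptions about plant count or spacing, and one parameter
set that works across sensors and training systems.

## Method

The pipeline has three stages:

1. **Ground/plant separation.** Cloth-simulation filtering (CSF): the
   cloud is inverted in z and a simulated cloth of grid resolution
   GR = 0.3 m settles onto it under gravity with stiffness constraints; a
   point is ground iff its distance to the cloth is ≤ DT = 0.3 m. A
   terrain raster (per-cell 5th percentile, bilinear queries) then
   normalizes the plant cloud to heights above ground.
2. **Row segmentation.** The plant cloud is voxel-downsampled (0.1 m) and
   clustered in the xy-plane with DBSCAN (ε = 0.35 m, P<sub>min</sub> = 40).
   The row orientation θ is a point-count-weighted axial mean of
   per-cluster principal axes; after rotating rows parallel to the
   y-axis, clusters whose centroids lie within d = 1 m in |Δx| merge into
   one row (gaps, missing plants and posts over-segment rows; merging
   repairs them). Ground points join rows through per-row 3D bounding
   boxes.
3. **Row parameters.** Per ground row, each 0.05 m-downsampled point gets
   a sphericity S<sub>λ</sub> = λ₃/λ₁ from the eigenvalues
   (λ₁ ≥ λ₂ ≥ λ₃ ≥ 0) of its R = 0.25 m neighborhood covariance; ground
   is planar (S<sub>λ</sub> ≈ 0), trunk bases are 3D (high
   S<sub>λ</sub>). Candidates above a per-row Otsu threshold are
   clustered (DBSCAN, ε = 0.10 m, P<sub>min</sub> = 5) and each cluster
   centroid is a trunk position. Per plant row, 250 equal segments along
   the row yield plant height (mean of the top height decile), canopy
   width (top minus bottom decile means of the cross-row coordinate),
   canopy volume (3D alpha-shape at α = 0.3 m, after statistical outlier
   removal) and canopy lower bound (bottom decile mean).

Evaluation utilities score row segmentation by dominant-overlap fractions
against reference labels and trunk detection by precision/recall/F1 with
greedy one-to-one matching inside a 15 cm radius. A synthetic vineyard
generator (sloped terrain, rows at arbitrary bearing, irregular spacing,
two canopy morphologies, gaps, missing plants, posts, sensor noise)
provides full ground truth so every stage is testable without field data.

## Worked example

```r
library(vinerows)

vy <- generate_vineyard(vineyard_config(seed = 1))
vy
#> <vineyard> 7 rows (SMPH+VSP) | 75043 points | 175 trunks | bearing 20 deg, slope 5 deg

res <- run_pipeline(pipeline_config(), cloud = vy$cloud)
res
#> <pipeline_result> 75043 points -> 49845 ground / 25198 plant | 7 rows | 174 trunks (8.3 s)

match_trunks(as.matrix(res$trunks[, c("x", "y")]),
             as.matrix(vy$truth$trunks[, c("x", "y")]))
#> <detection_evaluation> TP 174  FP 0  FN 1 | precision 100%  recall 99%  F1 100% (radius 0.15 m)

attr(res$profiles[["1"]], "summary")[, 1:4]   # an SMPH row
#> mean_height_m 1.62 | sd 0.07 | mean_width_m 0.59 | sd 0.06
```

The scene's 7 planted rows are recovered exactly (the row model's θ is
19.9° against the configured 20° bearing); 174 of 175 trunks are found
with no false positive, the miss being a trunk whose canopy-carved
neighborhood left too few candidate points. Row-level summaries show the
expected training-system contrast -- the SMPH row above is taller, wider
and more voluminous than a VSP row from the same scene (height 1.48 m,
width 0.24 m). `pipeline_report(res, "report/")` renders the per-row
curves (height + lower bound with trunk overlays, width, volume) and
histograms; a command-line front end with `simulate`, `separate`, `rows`,
`trunks`, `profile`, `evaluate`, `run` and `report` subcommands lives at
`inst/cli/vinerows.R`.

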