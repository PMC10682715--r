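# Small synthetic scenes shared across test files. Everything is built in
# code at test time; the full-size default scene is reserved for the
# acceptance suite.

# a compact vineyard that runs through the whole pipeline in ~1 s
tiny_vineyard_config <- function(seed = 1, slope = 4, bearing = 15,
                                 presets = c("SMPH", "VSP"), ...) {
  vineyard_config(n_rows = 3L, row_length = 8, presets = presets,
                  bearing = bearing, slope = slope, seed = seed, ...)
}

# flat ground strip with vertical trunk cylinders at known x positions,
# the clean geometry behind the trunk-detection examples
flat_trunk_fixture <- function(n_trunks = 10, spacing = 1.2, seed = 42,
                               trunk_points = 60, noise_sd = 0.005) {
  set.seed(seed)
  width <- 2
  len <- n_trunks * spacing + 2
  ng <- round(len * width * 150)
  gx <- runif(ng, 0, len); gy <- runif(ng, -width / 2, width / 2)
  pts <- cbind(gx, gy, 0)
  centers <- cbind(x = seq(1, by = spacing, length.out = n_trunks), y = 0)
  for (i in seq_len(n_trunks)) {
    a <- runif(trunk_points, 0, 2 * pi)
    pts <- rbind(pts, cbind(centers[i, 1] + 0.05 * cos(a),
                            centers[i, 2] + 0.05 * sin(a),
                            runif(trunk_points, 0, 0.4)))
  }
  pts <- pts + rnorm(length(pts), 0, noise_sd)
  list(cloud = point_cloud(pts), centers = centers)
}

# uniform volumetric slab: the analytic benchmark for the percentile
# estimators (top-decile mean of U(a, b) = b - 0.05 (b - a), bottom-decile
# mean = a + 0.05 (b - a))
slab_cloud <- function(n = 4000, zlim = c(0.8, 1.8), xlim = c(0, 0.4),
                       ylim = c(0, 1), seed = 1) {
  set.seed(seed)
  point_cloud(cbind(runif(n, xlim[1], xlim[2]),
                    runif(n, ylim[1], ylim[2]),
                    runif(n, zlim[1], zlim[2])))
}

# ground separation + height normalization + row segmentation, scored by
# dominant overlap against the generator's labels on the plant partition
pipeline_row_accuracy <- function(vy) {
  sep <- csf_ground_filter(vy$cloud)
  tm <- build_terrain_model(sep$ground)
  model <- segment_rows(normalize_heights(sep$plant, tm))
  ref <- vy$truth$labels$row[sep$plant_idx]
  row_segmentation_accuracy(model$labels, ifelse(is.na(ref), -1L, ref))
}
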