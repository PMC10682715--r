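test_that("sphericity vanishes on planes and lines", {
  set.seed(40)
  plane <- point_cloud(cbind(runif(1500), runif(1500), 0))
  sp <- compute_sphericity(plane, feature_params(voxel = 0.02))
  expect_true(all(pc_attr(sp$cloud, "sphericity") < 1e-12))

  line <- point_cloud(cbind(seq(0, 5, 0.01), 0, 0))
  sl <- compute_sphericity(line, feature_params(voxel = 0.005))
  expect_true(all(pc_attr(sl$cloud, "sphericity") < 1e-12))
})

test_that("sphericity approaches 1 on a dense sphere and matches a brute-force scan", {
  set.seed(41)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 0.1
  sp <- compute_sphericity(point_cloud(u), feature_params(radius = 0.25,
                                                          voxel = 0.004))
  s <- pc_attr(sp$cloud, "sphericity")
  expect_gt(mean(s), 0.95)

  # brute-force neighborhood covariance on a small subsample
  ds <- sp$cloud$coords
  for (i in sample(nrow(ds), 5)) {
    nb <- which(sqrt(rowSums(sweep(ds, 2, ds[i, ])^2)) <= 0.25)
    cv <- stats::cov(ds[nb, , drop = FALSE]) * (length(nb) - 1) / length(nb)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(s[i], ev[3] / ev[1], tolerance = 1e-9)
  }
})

test_that("sphericity is invariant under rigid motion", {
  set.seed(42)
  pts <- matrix(runif(900, 0, 2), ncol = 3)
  base <- compute_sphericity(point_cloud(pts), feature_params(voxel = 0.001))
  ang <- 0.9
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- compute_sphericity(point_cloud(pts %*% t(R) + 5),
                              feature_params(voxel = 0.001))
  # voxel 0.001 keeps every point, so fields align point for point
  s0 <- pc_attr(base$cloud, "sphericity")
  s1 <- pc_attr(moved$cloud, "sphericity")
  expect_equal(sort(s1), sort(s0), tolerance = 1e-9)
  expect_true(all(s0 >= 0 & s0 <= 1))
})

test_that("otsu separates a bimodal mixture and handles degenerate input", {
  v <- c(rep(0.1, 50), rep(0.9, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  expect_error(otsu_threshold(rep(0.5, 10)), "degenerate histogram")
})

test_that("otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(43)
  for (i in 1:10) {
    v <- c(rnorm(300, 0.05, 0.01), rnorm(200, 0.6, 0.05))
    v <- pmin(pmax(v, 0), 1)
    expect_equal(otsu_threshold(v), otsu_exhaustive(v), tolerance = 1e-12)
    expect_lt(abs(otsu_threshold(v) - otsu_exhaustive(v)), 0.05)
  }
  # random (not necessarily bimodal) inputs
  for (i in 1:10) {
    v <- runif(sample(50:500, 1))
    expect_equal(otsu_threshold(v), otsu_exhaustive(v), tolerance = 1e-12)
  }
})

test_that("otsu is symmetric under value reflection", {
  set.seed(44)
  # reflecting the data reflects the split: thresholds may land on opposite
  # ends of an empty between-class plateau (ties break toward the lower
  # edge), but no data point may separate them, so the induced two-class
  # partition is identical
  for (i in 1:5) {
    v <- c(rbeta(400, 2, 8), rbeta(100, 8, 2))
    thr <- otsu_threshold(v)
    mirrored <- min(v) + max(v) - otsu_threshold(min(v) + max(v) - v)
    lo <- min(thr, mirrored); hi <- max(thr, mirrored)
    expect_false(any(v > lo + 1e-12 & v < hi - 1e-12))
    expect_equal(sum(v > hi), sum(v > lo + 1e-12))
  }
})

test_that("trunks rising from flat ground are detected within 15 cm", {
  fx <- flat_trunk_fixture(n_trunks = 10, spacing = 1.2)
  ts <- detect_trunks(fx$cloud)
  expect_equal(nrow(ts$positions), 10)
  ev <- match_trunks(ts$positions[, 1:2], fx$centers, radius = 0.15)
  expect_equal(ev$tp, 10)
  expect_equal(ev$fp, 0)
})

test_that("a trunk-free planar floor yields an empty trunk set", {
  set.seed(45)
  floor_only <- point_cloud(cbind(runif(3000, 0, 5), runif(3000, 0, 2), 0))
  expect_message(ts <- detect_trunks(floor_only), "no trunk candidates")
  expect_equal(nrow(ts$positions), 0)
})

test_that("two nearby trunks separated by more than eps stay distinct", {
  set.seed(46)
  g <- cbind(runif(4000, 0, 3), runif(4000, 0, 2), rnorm(4000, 0, 0.004))
  mk <- function(cx) {
    a <- runif(80, 0, 2 * pi)
    cbind(cx + 0.02 * cos(a), 1 + 0.02 * sin(a), runif(80, 0, 0.4))
  }
  cloud <- point_cloud(rbind(g, mk(1.2), mk(1.75)))  # 0.55 m apart
  ts <- detect_trunks(cloud)
  expect_equal(nrow(ts$positions), 2)
  expect_equal(sort(ts$positions[, 1]), c(1.2, 1.75), tolerance = 0.05)
})

test_that("degrading trunk sampling lowers recall while precision holds", {
  recalls <- c(); precisions <- c()
  for (drop in c(0, 0.5, 0.8)) {
    vy <- generate_vineyard(tiny_vineyard_config(seed = 9,
                                                 trunk_dropout = drop,
                                                 presets = "SMPH"))
    res <- run_pipeline(pipeline_config(), cloud = vy$cloud,
                        do_profiles = FALSE)
    ev <- match_trunks(as.matrix(res$trunks[, c("x", "y")]),
                       as.matrix(vy$truth$trunks[, c("x", "y")]))
    recalls <- c(recalls, ev$recall)
    precisions <- c(precisions, ev$precision)
  }
  expect_true(all(diff(recalls) <= 0.01))   # monotone degradation
  expect_lt(recalls[3], recalls[1])
  expect_true(all(precisions >= 0.9, na.rm = TRUE))
})
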