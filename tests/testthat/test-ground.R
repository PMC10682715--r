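test_that("cloth filter separates an obvious outlier from a flat plane", {
  set.seed(20)
  g <- cbind(runif(500, 0, 5), runif(500, 0, 5), 0)
  cloud <- point_cloud(rbind(g, c(2.5, 2.5, 1)))
  sep <- csf_ground_filter(cloud)
  expect_equal(length(sep$ground_idx), 500)
  expect_equal(sep$plant_idx, 501L)
  # partition property
  expect_equal(sort(c(sep$ground_idx, sep$plant_idx)), 1:501)
})

test_that("everything within DT of a common plane is ground", {
  set.seed(21)
  cloud <- point_cloud(cbind(runif(300, 0, 4), runif(300, 0, 4),
                             runif(300, 0, 0.2)))
  sep <- csf_ground_filter(cloud)
  expect_equal(n_points(sep$plant), 0)
})

test_that("cloth filter needs enough points", {
  expect_error(csf_ground_filter(point_cloud(rbind(c(0, 0, 0)))),
               "insufficient points")
})

test_that("sloped terrain with canopy blobs is classified at >= 99%", {
  vy <- generate_vineyard(tiny_vineyard_config(seed = 3, slope = 10))
  sep <- csf_ground_filter(vy$cloud)
  cls <- vy$truth$labels$class
  is_ground_pred <- logical(n_points(vy$cloud))
  is_ground_pred[sep$ground_idx] <- TRUE
  expect_gte(mean(is_ground_pred[cls == "ground"]), 0.99)
  expect_gte(mean(!is_ground_pred[cls == "canopy"]), 0.99)
})

test_that("classification accuracy is slope invariant within one point", {
  acc <- vapply(c(0, 10), function(sl) {
    vy <- generate_vineyard(tiny_vineyard_config(seed = 4, slope = sl))
    sep <- csf_ground_filter(vy$cloud)
    cls <- vy$truth$labels$class
    pred_ground <- logical(n_points(vy$cloud))
    pred_ground[sep$ground_idx] <- TRUE
    truth_ground <- cls == "ground"
    mean(pred_ground == truth_ground)
  }, 0)
  expect_lt(abs(acc[1] - acc[2]), 0.01)
})

test_that("the ground set is non-shrinking in DT", {
  vy <- generate_vineyard(tiny_vineyard_config(seed = 5))
  sizes <- vapply(c(0.1, 0.3, 0.6), function(dt)
    length(csf_ground_filter(vy$cloud,
                             ground_filter_params(dt = dt))$ground_idx), 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("terrain model reproduces constant and linear fields", {
  set.seed(22)
  flat <- point_cloud(cbind(runif(2000, 0, 10), runif(2000, 0, 10), 2))
  tm <- build_terrain_model(flat)
  q <- terrain_elevation(tm, runif(50, 1, 9), runif(50, 1, 9))
  expect_equal(q, rep(2, 50), tolerance = 1e-6)

  x <- runif(4000, 0, 20); y <- runif(4000, 0, 10)
  ramp <- point_cloud(cbind(x, y, 0.1 * x))
  tm2 <- build_terrain_model(ramp)
  expect_equal(terrain_elevation(tm2, 10, 5), 1.0, tolerance = 0.3 * 0.1 + 0.02)

  single <- point_cloud(cbind(runif(30, 0, 0.2), runif(30, 0, 0.2), 5))
  tm3 <- build_terrain_model(single)
  expect_equal(terrain_elevation(tm3, 0.1, 0.1), 5, tolerance = 1e-6)
  expect_error(build_terrain_model(point_cloud(NULL)), "ground")
})

test_that("height normalization subtracts the local terrain elevation", {
  set.seed(23)
  gx <- runif(3000, 0, 10); gy <- runif(3000, 0, 10)
  ground <- point_cloud(cbind(gx, gy, 1))
  tm <- build_terrain_model(ground)
  plant <- point_cloud(rbind(c(5, 5, 3)))
  expect_equal(unname(normalize_heights(plant, tm)$coords[1, 3]), 2,
               tolerance = 1e-6)
  # points on the surface normalize to ~0, and the operation is invertible
  surf <- point_cloud(cbind(runif(200, 1, 9), runif(200, 1, 9), 1))
  norm <- normalize_heights(surf, tm)
  expect_lt(max(abs(norm$coords[, 3])), 0.02)
  e <- terrain_elevation(tm, surf$coords[, 1], surf$coords[, 2])
  expect_equal(norm$coords[, 3] + e, surf$coords[, 3], tolerance = 1e-9)
})

test_that("normalized canopy height matches the generator on a slope", {
  vy <- generate_vineyard(tiny_vineyard_config(seed = 6, slope = 10))
  sep <- csf_ground_filter(vy$cloud)
  tm <- build_terrain_model(sep$ground)
  norm <- normalize_heights(sep$plant, tm)
  lab <- vy$truth$labels[sep$plant_idx, ]
  canopy <- lab$class == "canopy"
  # normalized heights should match the generated height-above-ground
  err <- norm$coords[canopy, 3] - lab$height[canopy]
  expect_lt(abs(stats::median(err)), 0.05)
})
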