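test_that("dbscan finds well-separated blobs and flags isolated noise", {
  set.seed(30)
  blob <- function(cx) cbind(rnorm(50, cx, 0.1), rnorm(50, 0, 0.1))
  x <- rbind(blob(0), blob(5))
  lab <- dbscan(x, cluster_params(eps = 0.35, min_points = 40L))
  expect_equal(length(unique(lab)), 2)
  expect_false(any(lab == -1))

  iso <- cbind(seq(0, 18, by = 2), 0)
  expect_true(all(dbscan(iso, cluster_params(eps = 0.35, min_points = 5L)) == -1))
})

test_that("dbscan agrees with the brute-force density-connectivity oracle", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(50:300, 1)
    d <- sample(2:3, 1)
    x <- matrix(runif(n * d, 0, 3), ncol = d)
    eps <- runif(1, 0.2, 0.5)
    mp <- sample(3:6, 1)
    expect_true(same_partition(dbscan(x, cluster_params(eps, mp)),
                               brute_dbscan(x, eps, mp)),
                info = sprintf("instance %d (n=%d, d=%d)", i, n, d))
  }
})

test_that("row orientation is recovered exactly for a collinear cluster", {
  th <- 30 * pi / 180
  t <- seq(0, 10, by = 0.1)
  pts <- cbind(sin(th) * t, cos(th) * t)   # direction 30 deg from +y
  est <- estimate_row_orientation(pts, rep(0L, nrow(pts)))
  expect_equal(est, th, tolerance = 1e-6)
  expect_error(estimate_row_orientation(pts[1, , drop = FALSE], -1L),
               "cannot estimate orientation")
})

test_that("orientation from noisy parallel rows is within half a degree", {
  set.seed(32)
  th <- 25 * pi / 180
  pts <- NULL; lab <- NULL
  for (r in 0:2) {
    t <- runif(400, 0, 20)
    x <- sin(th) * t + r * 2 * cos(th) + rnorm(400, 0, 0.05)
    y <- cos(th) * t - r * 2 * sin(th) + rnorm(400, 0, 0.05)
    pts <- rbind(pts, cbind(x, y)); lab <- c(lab, rep(r, 400))
  }
  est <- estimate_row_orientation(pts, as.integer(lab))
  expect_lt(abs(est - th) * 180 / pi, 0.5)
})

test_that("orientation is axial: antipodal directions give the same angle", {
  t <- seq(0.1, 5, by = 0.1)
  th <- 0.4
  u <- cbind(sin(th) * t, cos(th) * t)
  pts <- rbind(u, -u)
  lab <- c(rep(0L, nrow(u)), rep(1L, nrow(u)))
  expect_equal(estimate_row_orientation(pts, lab),
               estimate_row_orientation(u, rep(0L, nrow(u))),
               tolerance = 1e-9)
})

test_that("centroid merging joins same-row fragments and keeps rows apart", {
  set.seed(33)
  frag <- function(cx, y0) cbind(rnorm(30, cx, 0.05), runif(30, y0, y0 + 3))
  pts <- rbind(frag(10.0, 0), frag(10.4, 5), frag(12.0, 0))
  lab <- c(rep(0L, 30), rep(1L, 30), rep(2L, 30))
  merged <- merge_row_clusters(pts, lab, merge_params(1.0))
  expect_equal(merged[1], merged[31])      # |dx| = 0.4 < 1 merged
  expect_false(merged[1] == merged[61])    # |dx| = 2.0 >= 1 separate
  expect_equal(length(unique(merged)), 2)
  # a short post-like fragment at the row x joins the row
  post <- cbind(rnorm(10, 10.05, 0.02), runif(10, 9, 9.2))
  merged2 <- merge_row_clusters(rbind(pts, post), c(lab, rep(3L, 10)),
                                merge_params(1.0))
  expect_equal(merged2[91], merged2[1])
})

test_that("segment_rows recovers the planted rows of a small vineyard", {
  vy <- generate_vineyard(tiny_vineyard_config(seed = 7))
  sep <- csf_ground_filter(vy$cloud)
  tm <- build_terrain_model(sep$ground)
  model <- segment_rows(normalize_heights(sep$plant, tm))
  expect_equal(model$n_rows, 3)
  expect_equal(abs(model$theta) * 180 / pi, 15, tolerance = 1)
  # rows lie along y after rotation
  for (r in model$rows) {
    sp <- r$plant_box$max - r$plant_box$min
    expect_lt(sp[1], sp[2])
  }
  # label propagation reaches nearly all full-resolution points
  expect_gte(mean(!is.na(model$labels)), 0.99)
})

test_that("a canopy gap splits a row into clusters that merging repairs", {
  set.seed(34)
  # one straight row with a 0.8 m empty stretch in the middle
  y <- c(runif(2500, 0, 6), runif(2500, 6.8, 13))
  pts <- cbind(rnorm(5000, 0, 0.15), y, runif(5000, 0.5, 1.5))
  model <- segment_rows(point_cloud(pts))
  expect_equal(model$n_rows, 1)
})

test_that("zero clusters is reported as an error", {
  sparse <- point_cloud(cbind(seq(0, 20, 2), 0, 1))
  expect_error(segment_rows(sparse), "no rows detected")
})

test_that("ground rows collect the points under each row's box", {
  vy <- generate_vineyard(tiny_vineyard_config(seed = 8))
  sep <- csf_ground_filter(vy$cloud)
  tm <- build_terrain_model(sep$ground)
  model <- segment_rows(normalize_heights(sep$plant, tm))
  model <- segment_ground_rows(sep$ground, model)
  expect_equal(sort(unique(stats::na.omit(model$ground_labels))), 1:3)
  # generated trunk points that CSF sent to ground land in a row's ground set
  lab <- vy$truth$labels[sep$ground_idx, ]
  trunk_pts <- which(lab$class == "trunk")
  expect_gte(mean(!is.na(model$ground_labels[trunk_pts])), 0.99)
  # and carry the correct row
  ok <- model$ground_labels[trunk_pts] == lab$row[trunk_pts]
  expect_gte(mean(ok, na.rm = TRUE), 0.99)
  # an alley point midway between rows stays unassigned: rows are 2 m
  # apart and boxes hug the canopy, so check some alley ground exists
  alley <- which(is.na(model$ground_labels))
  expect_gt(length(alley), 0)
})
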