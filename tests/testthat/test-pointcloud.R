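test_that("point_cloud enforces its invariants", {
  expect_error(point_cloud(matrix(1, 2, 2)), "N x 3")
  expect_error(point_cloud(rbind(c(0, 0, NA))), "finite")
  expect_error(point_cloud(rbind(c(0, 0, 0)), attrs = list(class = 1:2)),
               "one entry per point")
  expect_error(point_cloud(rbind(c(0, 0, 0)), attrs = list(row_id = -2L)),
               "row_id")
  expect_error(point_cloud(rbind(c(0, 0, 0)), attrs = list(sphericity = 1.2)),
               "sphericity")
  pc <- point_cloud(NULL)
  expect_equal(n_points(pc), 0)
  expect_error(bbox3d(c(0, 0, 1), c(1, 1, 0)), "min <= max")
})

test_that("voxel downsampling merges co-voxel points into centroids", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(0.01, 0, 0)))
  out <- voxel_downsample(pc, 0.1)
  expect_equal(n_points(out), 1)
  expect_equal(unname(out$coords[1, ]), c(0.005, 0, 0))

  pc2 <- point_cloud(rbind(c(0, 0, 0), c(0.25, 0, 0)))
  out2 <- voxel_downsample(pc2, 0.1)
  expect_equal(n_points(out2), 2)
  expect_equal(sort(out2$coords[, 1]), c(0, 0.25))
})

test_that("voxel downsampling matches a brute-force occupancy tally", {
  set.seed(7)
  pc <- point_cloud(matrix(runif(3e4), ncol = 3))
  out <- voxel_downsample(pc, 0.1)
  occ <- unique(floor(pc$coords / 0.1))
  expect_equal(n_points(out), nrow(occ))
  expect_lte(n_points(out), 1000)
  # index maps every input point to its centroid's voxel
  vi <- attr(out, "voxel_index")
  expect_true(all(floor(out$coords[vi, ] / 0.1) == floor(pc$coords / 0.1)))
})

test_that("voxel downsampling is idempotent below the output spacing", {
  set.seed(8)
  pc <- point_cloud(matrix(runif(900, 0, 5), ncol = 3))
  once <- voxel_downsample(pc, 0.5)
  dmin <- min(stats::dist(once$coords))
  twice <- voxel_downsample(once, dmin * 0.9)
  expect_equal(n_points(twice), n_points(once))
  expect_equal(sort(twice$coords[, 1]), sort(once$coords[, 1]))
})

test_that("rotate_xy is a rigid motion of the horizontal plane", {
  set.seed(9)
  pc <- point_cloud(matrix(rnorm(300), ncol = 3))
  expect_equal(rotate_xy(pc, 0)$coords, pc$coords, tolerance = 1e-12)
  # composition: two quarter turns equal a half turn
  ab <- rotate_xy(rotate_xy(pc, pi / 2), pi / 2, attr(rotate_xy(pc, pi / 2), "pivot"))
  half <- rotate_xy(pc, pi)
  expect_lt(max(abs(ab$coords - half$coords)), 1e-9)
  # pairwise distances preserved
  rot <- rotate_xy(pc, 0.7)
  expect_lt(max(abs(stats::dist(rot$coords) - stats::dist(pc$coords))), 1e-9)
  # z untouched
  expect_equal(rot$coords[, 3], pc$coords[, 3])
})

test_that("rotating a bearing-theta segment by (pi/2 - theta) aligns it with y", {
  th <- 0.6
  seg <- point_cloud(cbind(cos(th) * seq(0, 5, 0.1),
                           sin(th) * seq(0, 5, 0.1), 0))
  rot <- rotate_xy(seg, pi / 2 - th)
  expect_lt(diff(range(rot$coords[, 1])), 1e-9)
})

test_that("crop_to_box keeps exactly the closed-box members", {
  box <- bbox3d(c(0, 0, 0), c(1, 1, 1))
  pc <- point_cloud(rbind(c(0.5, 0.5, 0.5), c(1.5, 0, 0), c(1, 1, 1)))
  kept <- crop_to_box(pc, box)
  expect_equal(n_points(kept), 2)          # boundary point kept, outlier not
  expect_true(all(kept$coords[, 1] <= 1))

  set.seed(10)
  cloud <- point_cloud(matrix(runif(600, -0.5, 1.5), ncol = 3))
  kept <- crop_to_box(cloud, box)
  manual <- apply(cloud$coords, 1, function(p) all(p >= 0 & p <= 1))
  expect_equal(n_points(kept), sum(manual))
  expect_equal(attr(kept, "index"), which(manual))
})
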