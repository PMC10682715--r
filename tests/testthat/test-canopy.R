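test_that("segment splitting is exact half-open bookkeeping", {
  set.seed(50)
  row <- point_cloud(cbind(runif(5000, -0.3, 0.3), c(0, 25, runif(4998, 0, 25)),
                           runif(5000, 0.5, 1.8)))
  segs <- split_into_segments(row, segmentation_scheme(n_segments = 250))
  expect_equal(nrow(segs$intervals), 250)
  expect_equal(unique(round(diff(t(segs$intervals))[1, ], 12)), 0.1)
  expect_equal(sum(lengths(segs$indices)), 5000)   # every point in one segment

  one <- split_into_segments(row, segmentation_scheme(n_segments = 1))
  expect_equal(lengths(one$indices), 5000)

  # interior boundary point belongs to the right-hand segment
  pts <- point_cloud(cbind(0, c(0, 1, 2), 0))
  s <- split_into_segments(pts, segmentation_scheme(n_segments = 2))
  expect_equal(s$indices[[2]], c(2L, 3L))
})

test_that("height and lower bound are decile means with linear percentiles", {
  z <- 1:100
  expect_equal(segment_height(as.numeric(z)), 95.5)
  expect_equal(canopy_lower_bound(as.numeric(z)), 5.5)
  expect_equal(segment_height(rep(1.3, 7)), 1.3)
  expect_equal(canopy_lower_bound(rep(2.5, 7)), 2.5)
  expect_true(is.na(segment_height(numeric(0))))
})

test_that("decile estimators recover analytic values on uniform slabs", {
  for (s in 1:10) {
    slab <- slab_cloud(seed = s)
    h <- segment_height(slab)
    lb <- canopy_lower_bound(slab)
    expect_equal(h, 1.75, tolerance = 0.05 / 1.75)
    expect_equal(lb, 0.85, tolerance = 0.05 / 0.85)
    expect_true(h >= 1.70 && h <= 1.80)
    expect_true(lb >= 0.80 && lb <= 0.90)
  }
})

test_that("canopy width is the trimmed cross-row extent", {
  set.seed(51)
  seg <- point_cloud(cbind(runif(5000, 0, 0.4), runif(5000), runif(5000)))
  w <- segment_width(seg)
  expect_equal(w, 0.36, tolerance = 0.012)
  expect_true(w >= 0.32 && w <= 0.40)

  flat <- point_cloud(cbind(0.2, runif(100), runif(100)))
  expect_equal(segment_width(flat), 0)

  walls <- point_cloud(cbind(rep(c(0, 0.5), each = 200), runif(400),
                             runif(400)))
  expect_equal(segment_width(walls), 0.5)
})

test_that("SOR removes isolated stragglers and keeps homogeneous clouds", {
  set.seed(52)
  blob <- cbind(runif(2000, 0, 1), runif(2000, 0, 1), runif(2000, 1, 1.6))
  strays <- cbind(runif(5, 0, 1), runif(5, 0, 1), runif(5, 0, 0.3))
  cloud <- point_cloud(rbind(blob, strays))
  filt <- sor_filter(cloud, k = 10, multiplier = 2)
  removed <- attr(filt, "removed")
  expect_true(all(2001:2005 %in% removed))       # every stray goes
  expect_lte(sum(removed <= 2000), 0.005 * 2000) # blob essentially intact

  grid <- as.matrix(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1),
                                z = 0:1))
  gf <- sor_filter(point_cloud(grid), k = 4, multiplier = 2)
  # regular grid: interior spacing uniform, only corner asymmetry possible
  expect_gte(n_points(gf), n_points(point_cloud(grid)) * 0.95)

  expect_warning(sor_filter(point_cloud(matrix(runif(9), 3)), k = 10),
                 "too few points")
})

test_that("SOR removal counts match the brute-force k-NN oracle", {
  set.seed(53)
  for (i in 1:5) {
    x <- matrix(runif(1500, 0, 2), ncol = 3)
    k <- sample(4:12, 1); mult <- runif(1, 1, 2.5)
    filt <- sor_filter(point_cloud(x), k, mult)
    d <- brute_knn_meandist(x, k)
    expect_equal(length(attr(filt, "removed")),
                 sum(d > mean(d) + mult * stats::sd(d)))
  }
})

test_that("alpha-shape volume: closed forms, monotonicity, hull limit", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(alpha_shape_volume(tet, Inf), 1 / 6, tolerance = 1e-9)
  expect_equal(alpha_shape_volume(tet, 10), 1 / 6, tolerance = 1e-9)

  expect_warning(v0 <- alpha_shape_volume(tet[1:3, ], 1), "fewer than 4")
  expect_equal(v0, 0)
  flat <- cbind(runif(30), runif(30), 0)
  expect_warning(vf <- alpha_shape_volume(flat, 1), "coplanar")
  expect_equal(vf, 0)

  set.seed(54)
  for (i in 1:10) {
    x <- matrix(runif(3 * sample(15:40, 1)), ncol = 3)
    alphas <- sort(runif(5, 0.05, 2))
    v <- alpha_shape_volume(x, c(alphas, Inf))
    expect_true(all(diff(v) >= -1e-12))
    expect_equal(v[6], brute_hull_volume(x), tolerance = 1e-9)
  }
})

test_that("alpha complex satisfies the empty-circumsphere property", {
  set.seed(55)
  x <- matrix(runif(90), ncol = 3)
  tets <- vinerows:::.delaunay_tets_cpp(x)
  for (i in seq_len(nrow(tets))) {
    v <- x[tets[i, ], ]
    A <- 2 * rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
    b <- rowSums(rbind(v[2, ], v[3, ], v[4, ])^2) - sum(v[1, ]^2)
    cc <- solve(A, b)
    r <- sqrt(sum((v[1, ] - cc)^2))
    d <- sqrt(rowSums(sweep(x, 2, cc)^2))
    expect_gte(min(d[-tets[i, ]]), r - 1e-7)
  }
})

test_that("a dense unit cube sample has alpha volume near 1", {
  set.seed(56)
  x <- matrix(runif(3 * 20000), ncol = 3)
  v <- alpha_shape_volume(x, 0.3)
  expect_equal(v, 1.0, tolerance = 0.1)
})

test_that("segment volume approximates the sampled slab volume", {
  set.seed(57)
  slab <- point_cloud(cbind(runif(6000, 0, 0.1), runif(6000, 0, 0.6),
                            runif(6000, 0, 1.0)))
  v <- segment_volume(slab, canopy_params())
  expect_equal(v, 0.06, tolerance = 0.15)
  expect_equal(segment_volume(point_cloud(NULL), canopy_params()), 0)
})

test_that("profile_row contrasts the two training systems as expected", {
  mk_row <- function(preset, seed) {
    vy <- generate_vineyard(vineyard_config(n_rows = 1L, row_length = 12,
                                            bearing = 0, slope = 0,
                                            presets = preset, seed = seed,
                                            margin = 1))
    lab <- vy$truth$labels
    keep <- which(lab$class %in% c("canopy", "trunk") & lab$height > 0.3)
    row <- pc_subset(vy$cloud, keep)
    row$coords[, 3] <- lab$height[keep]  # idealized normalization
    profile_row(row, segmentation_scheme(n_segments = 100))
  }
  smph <- attr(mk_row("SMPH", 58), "summary")
  vsp <- attr(mk_row("VSP", 58), "summary")
  expect_gt(smph$mean_height_m, vsp$mean_height_m)
  expect_gt(smph$mean_width_m, vsp$mean_width_m)
  expect_gt(smph$mean_volume_m3, vsp$mean_volume_m3)
})

test_that("a planted gap shows as an interruption in the height profile", {
  set.seed(59)
  y <- c(runif(3000, 0, 5), runif(3000, 5.5, 10.5))  # 0.5 m empty stretch
  row <- point_cloud(cbind(runif(6000, -0.2, 0.2), y, runif(6000, 0.6, 1.6)))
  prof <- profile_row(row, segmentation_scheme(segment_length = 0.1))
  gap_segs <- prof$y_start >= 5.02 & prof$y_end <= 5.48
  expect_gt(sum(gap_segs), 0)
  expect_true(all(is.na(prof$height_m[gap_segs])))
  expect_true(all(prof$n_points[gap_segs] == 0))
})

test_that("merging two adjacent segments mixes their percentile means", {
  set.seed(60)
  for (i in 1:5) {
    a <- runif(300, 0, 1.5); b <- runif(300, 0.5, 2)
    ha <- segment_height(a); hb <- segment_height(b)
    hab <- segment_height(c(a, b))
    expect_gte(hab, min(ha, hb) - 1e-12)
    expect_lte(hab, max(ha, hb) + 1e-12)
    la <- canopy_lower_bound(a); lb <- canopy_lower_bound(b)
    lab <- canopy_lower_bound(c(a, b))
    expect_gte(lab, min(la, lb) - 1e-12)
    expect_lte(lab, max(la, lb) + 1e-12)
  }
})

test_that("row-level height and width are stable across segment lengths", {
  set.seed(61)
  row <- point_cloud(cbind(runif(20000, -0.35, 0.35), runif(20000, 0, 25),
                           runif(20000, 0.5, 1.7)))
  fine <- attr(profile_row(row, segmentation_scheme(n_segments = 250)),
               "summary")
  coarse <- attr(profile_row(row, segmentation_scheme(segment_length = 1)),
                 "summary")
  expect_equal(fine$mean_height_m, coarse$mean_height_m, tolerance = 0.02)
  expect_equal(fine$mean_width_m, coarse$mean_width_m, tolerance = 0.05)
})
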