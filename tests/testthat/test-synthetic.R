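test_that("generation is deterministic for a fixed seed", {
  a <- generate_vineyard(tiny_vineyard_config(seed = 80))
  b <- generate_vineyard(tiny_vineyard_config(seed = 80))
  expect_identical(a$cloud$coords, b$cloud$coords)
  expect_identical(a$truth$trunks, b$truth$trunks)
  c <- generate_vineyard(tiny_vineyard_config(seed = 81))
  expect_false(identical(a$cloud$coords, c$cloud$coords))
})

test_that("missing-plant probability one leaves only ground and posts", {
  vy <- generate_vineyard(tiny_vineyard_config(seed = 82, missing_prob = 1,
                                               posts_per_row = 2L))
  expect_setequal(unique(vy$truth$labels$class), c("ground", "post"))
  expect_equal(nrow(vy$truth$trunks), 0)
})

test_that("scene construction arithmetic matches the configuration", {
  cfg <- vineyard_config(seed = 83)
  vy <- generate_vineyard(cfg)
  # one truth trunk per retained plant
  expect_equal(nrow(vy$truth$trunks), sum(vy$truth$rows$n_plants))
  # de-rotating the trunk positions puts adjacent rows ~spacing apart in x
  ang <- cfg$bearing * pi / 180
  xy <- cbind(vy$truth$trunks$x, vy$truth$trunks$y)
  xr <- xy[, 1] * cos(ang) - xy[, 2] * sin(ang)
  cx <- sort(tapply(xr, vy$truth$trunks$row, mean))
  expect_equal(as.numeric(diff(cx)), rep(2, 6), tolerance = 0.05)
  # row labels cover every non-ground point
  lab <- vy$truth$labels
  expect_true(all(!is.na(lab$row[lab$class != "ground"])))
})

test_that("presets order the two training systems correctly", {
  smph <- vineyard_preset("SMPH"); vsp <- vineyard_preset("VSP")
  expect_gt(smph$canopy_height, vsp$canopy_height)
  expect_gt(smph$canopy_width, vsp$canopy_width)
  expect_gt(smph$canopy_height - smph$canopy_lower,
            vsp$canopy_height - vsp$canopy_lower)
  expect_error(vineyard_preset("GUYOT"), "unknown preset")
  # trunks sit below the canopy lower bound in both systems
  cfg <- vineyard_config()
  expect_lt(cfg$trunk_height, vsp$canopy_lower)
  expect_lt(cfg$trunk_height, smph$canopy_lower)
})

test_that("truth is self-consistent under the evaluation metrics", {
  vy <- generate_vineyard(tiny_vineyard_config(seed = 84))
  tr <- as.matrix(vy$truth$trunks[, c("x", "y")])
  ev <- match_trunks(tr, tr)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  lab <- vy$truth$labels$row
  lab <- ifelse(is.na(lab), -1L, lab)
  acc <- row_segmentation_accuracy(lab, lab)
  expect_equal(acc$rate, 1)
})

test_that("height normalization recovers configured canopy tops across slopes", {
  for (sl in c(0, 8, 15)) {
    vy <- generate_vineyard(tiny_vineyard_config(seed = 85, slope = sl,
                                                 presets = "SMPH"))
    sep <- csf_ground_filter(vy$cloud)
    tm <- build_terrain_model(sep$ground)
    norm <- normalize_heights(sep$plant, tm)
    lab <- vy$truth$labels[sep$plant_idx, ]
    canopy <- which(lab$class == "canopy")
    top <- stats::quantile(norm$coords[canopy, 3], 0.99, names = FALSE)
    expect_equal(top, vineyard_preset("SMPH")$canopy_height,
                 tolerance = 0.05 / 1.7)
  }
})

test_that("occlusion coupling makes dense canopies lose more trunk points", {
  cfg_s <- tiny_vineyard_config(seed = 86, trunk_dropout = 0.5,
                                presets = "SMPH")
  cfg_v <- tiny_vineyard_config(seed = 86, trunk_dropout = 0.5,
                                presets = "VSP")
  n_tr <- function(cfg) sum(generate_vineyard(cfg)$truth$labels$class == "trunk")
  expect_lt(n_tr(cfg_s), n_tr(cfg_v))
})
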