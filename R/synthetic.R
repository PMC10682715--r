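#' Canopy morphology presets
#'
#' Two vine training systems with distinct canopy morphologies:
#' `"SMPH"` (semi-minimal pruned hedge) leaves branches in the trellis and
#' grows a tall, wide, nearly continuous canopy; `"VSP"` (vertical shoot
#' positioning) keeps one maintained trunk and a narrower, sparser canopy
#' that leaves more of the trunk visible. The preset dimensions are
#' plausible mid-season values for the two systems; SMPH strictly exceeds
#' VSP in canopy height, width and cross-section. The `occlusion` factor
#' scales the configured trunk dropout: a denser canopy occludes more of
#' the trunk during reconstruction.
#'
#' @param name `"SMPH"` or `"VSP"`.
#' @return a list of preset canopy parameters.
#' @export
vineyard_preset <- function(name) {
  switch(toupper(name),
    SMPH = list(name = "SMPH", canopy_height = 1.7, canopy_width = 0.7,
                canopy_lower = 0.5, continuity = 1.0, occlusion = 1.0),
    VSP = list(name = "VSP", canopy_height = 1.6, canopy_width = 0.35,
               canopy_lower = 0.7, continuity = 0.85, occlusion = 0.4),
    stop(sprintf("unknown preset '%s' (use SMPH or VSP)", name)))
}

#' Configuration of a synthetic vineyard scene
#'
#' Defines the generated scene: a sloped ground surface sampled on a
#' jittered grid, parallel vine rows at a global bearing with irregular
#' plant spacing, thin vertical trunks partially hidden under the canopy,
#' two canopy morphologies, optional metal posts, canopy gaps and missing
#' plants, and isotropic Gaussian sensor noise. Everything the generator
#' places is recorded as ground truth, so every pipeline stage can be
#' scored without external data.
#'
#' @param n_rows number of rows (3-10 is typical).
#' @param row_spacing distance between adjacent rows, meters.
#' @param row_length along-row extent, meters.
#' @param bearing row direction in degrees from the y-axis.
#' @param slope,aspect terrain slope in degrees and downhill azimuth in
#'   degrees (0 = +x).
#' @param plant_spacing,plant_jitter mean vine spacing and its uniform
#'   jitter, meters ("irregular vine spacing").
#' @param missing_prob probability that a plant (trunk + canopy) is
#'   absent.
#' @param gap_prob probability of a canopy gap at a plant (canopy removed,
#'   trunk kept).
#' @param gap_length range (2-vector, meters) of canopy gap lengths.
#' @param presets character vector of per-row training systems, recycled
#'   over rows.
#' @param trunk_height,trunk_radius,trunk_points trunk cylinder geometry
#'   and the number of surface samples per trunk.
#' @param trunk_dropout probability that a trunk point is lost to
#'   occlusion, scaled per row by the preset's `occlusion` factor.
#' @param posts_per_row number of metal posts per row (0 disables).
#' @param post_height,post_radius post geometry, meters.
#' @param canopy_density canopy volumetric sampling density, points/m^3.
#' @param ground_density ground sampling density, points/m^2.
#' @param density_scale global density multiplier (10 approximates a
#'   denser LiDAR survey).
#' @param noise_sd isotropic Gaussian noise, meters.
#' @param margin ground margin beyond the outer rows, meters.
#' @param seed RNG seed; a fixed seed reproduces the scene byte for byte.
#' @return an object of class `vineyard_config`.
#' @export
vineyard_config <- function(n_rows = 7L, row_spacing = 2.0, row_length = 25.0,
                            bearing = 20, slope = 5, aspect = 0,
                            plant_spacing = 1.0, plant_jitter = 0.15,
                            missing_prob = 0.05, gap_prob = 0.08,
                            gap_length = c(0.4, 0.9),
                            presets = c("SMPH", "SMPH", "SMPH",
                                        "VSP", "VSP", "VSP", "VSP"),
                            trunk_height = 0.4, trunk_radius = 0.05,
                            trunk_points = 60L, trunk_dropout = 0,
                            posts_per_row = 0L, post_height = 1.8,
                            post_radius = 0.03,
                            canopy_density = 250, ground_density = 100,
                            density_scale = 1, noise_sd = 0.01,
                            margin = 1.5, seed = 1L) {
  stopifnot(n_rows >= 1, row_spacing > 0, row_length > 0,
            plant_spacing > 0, plant_jitter >= 0,
            missing_prob >= 0, missing_prob <= 1,
            gap_prob >= 0, gap_prob <= 1, length(gap_length) == 2,
            trunk_height > 0, trunk_radius > 0, trunk_points >= 0,
            trunk_dropout >= 0, trunk_dropout <= 1,
            canopy_density > 0, ground_density > 0, density_scale > 0,
            noise_sd >= 0, margin >= 0)
  presets <- rep_len(presets, n_rows)
  lapply(presets, vineyard_preset)  # validates names
  structure(list(
    n_rows = as.integer(n_rows), row_spacing = row_spacing,
    row_length = row_length, bearing = bearing, slope = slope,
    aspect = aspect, plant_spacing = plant_spacing,
    plant_jitter = plant_jitter, missing_prob = missing_prob,
    gap_prob = gap_prob, gap_length = gap_length, presets = presets,
    trunk_height = trunk_height, trunk_radius = trunk_radius,
    trunk_points = as.integer(trunk_points), trunk_dropout = trunk_dropout,
    posts_per_row = as.integer(posts_per_row), post_height = post_height,
    post_radius = post_radius, canopy_density = canopy_density,
    ground_density = ground_density, density_scale = density_scale,
    noise_sd = noise_sd, margin = margin, seed = as.integer(seed)),
    class = "vineyard_config")
}

# point class codes used on generated clouds
.vy_class <- c(ground = 2L, canopy = 5L, trunk = 64L, post = 65L)

#' Generate a synthetic vineyard with ground truth
#'
#' Builds the scene described by the configuration in a local frame (rows
#' along y), applies the terrain elevation, rotates the whole scene to the
#' configured bearing, adds isotropic sensor noise and shuffles the point
#' order. Deterministic for a fixed seed.
#'
#' @param config a [vineyard_config()] object.
#' @return a list of class `vineyard` with `cloud` (a `point_cloud` with
#'   `class` and `row_id` attributes) and `truth`: per-point `labels`
#'   (tibble: class, row, terrain_z, height), `trunks` (tibble: row,
#'   plant, x, y, z at the trunk base, world frame), `rows` (tibble of
#'   per-row presets and true canopy dimensions), and the `config`.
#' @export
generate_vineyard <- function(config = vineyard_config()) {
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  ds <- config$density_scale
  half_w <- (config$n_rows - 1) * config$row_spacing / 2
  x0 <- -half_w - config$margin; x1 <- half_w + config$margin
  y0 <- -config$margin; y1 <- config$row_length + config$margin
  sl <- tan(config$slope * pi / 180)
  az <- config$aspect * pi / 180
  terrain_z <- function(x, y) sl * (cos(az) * x + sin(az) * y)

  px <- numeric(0); py <- numeric(0); ph <- numeric(0)  # height above ground
  pclass <- character(0); prow <- integer(0); pplant <- integer(0)

  add <- function(x, y, h, cls, row, plant) {
    px <<- c(px, x); py <<- c(py, y); ph <<- c(ph, h)
    pclass <<- c(pclass, rep(cls, length(x)))
    prow <<- c(prow, rep(as.integer(row), length(x)))
    pplant <<- c(pplant, rep(as.integer(plant), length(x)))
  }

  # ground: jittered grid over the full extent
  gs <- 1 / sqrt(config$ground_density * ds)
  gx <- seq(x0, x1, by = gs); gy <- seq(y0, y1, by = gs)
  gxy <- expand.grid(x = gx, y = gy)
  gxj <- gxy$x + stats::runif(nrow(gxy), -gs / 2, gs / 2)
  gyj <- gxy$y + stats::runif(nrow(gxy), -gs / 2, gs / 2)
  add(gxj, gyj, rep(0, length(gxj)), "ground", NA, NA)

  trunks <- NULL
  row_info <- NULL
  for (r in seq_len(config$n_rows)) {
    preset <- vineyard_preset(config$presets[r])
    cx <- -half_w + (r - 1) * config$row_spacing
    # irregular plant positions along the row
    yp <- numeric(0); yy <- 0
    while (yy <= config$row_length) {
      yp <- c(yp, yy)
      yy <- yy + config$plant_spacing +
        stats::runif(1, -config$plant_jitter, config$plant_jitter)
    }
    present <- stats::runif(length(yp)) >= config$missing_prob
    gap <- stats::runif(length(yp)) < config$gap_prob
    glen <- stats::runif(length(yp), config$gap_length[1], config$gap_length[2])
    # defects are sparse and interior: nearby defects (missing plants or
    # gaps) would compound into openings far beyond the configured gap
    # length, and a defect at the row end would leave a stub row -- not
    # the defect regime this scene emulates
    if (config$missing_prob < 1 && length(yp) > 4) {
      edge <- c(1, 2, length(yp) - 1, length(yp))
      present[edge] <- TRUE
      gap[edge] <- FALSE
      for (p in 3:(length(yp) - 2)) {
        if (!present[p - 1] || gap[p - 1] || !present[p - 2] || gap[p - 2]) {
          present[p] <- TRUE
          gap[p] <- FALSE
        }
      }
    }
    dropout <- min(1, config$trunk_dropout * preset$occlusion)
    for (p in seq_along(yp)) {
      if (!present[p]) next
      # trunk: cylinder-surface samples, thinned by occlusion dropout
      ntr <- stats::rbinom(1, round(config$trunk_points * ds), 1 - dropout)
      if (ntr > 0) {
        a <- stats::runif(ntr, 0, 2 * pi)
        hz <- stats::runif(ntr, 0, config$trunk_height)
        add(cx + config$trunk_radius * cos(a),
            yp[p] + config$trunk_radius * sin(a), hz, "trunk", r, p)
      }
      trunks <- rbind(trunks,
                      data.frame(row = r, plant = p, x = cx, y = yp[p]))
      # canopy: volumetric box per plant. A gap is carved symmetrically
      # around the boundary to the previous plant, eating the facing edges
      # of both canopies: the opening reaches the configured length while
      # every trunk stays under its own plant's remaining foliage and no
      # detached canopy island can form
      clen <- config$plant_spacing * preset$continuity
      ylo <- yp[p] - clen / 2
      yhi <- yp[p] + clen / 2
      if (gap[p])
        ylo <- max(ylo, yp[p] - config$plant_spacing / 2 + glen[p] / 2)
      if (p < length(yp) && gap[p + 1])
        yhi <- min(yhi, yp[p] + config$plant_spacing / 2 - glen[p + 1] / 2)
      cth <- preset$canopy_height - preset$canopy_lower
      if (yhi > ylo && cth > 0) {
        vol <- (yhi - ylo) * preset$canopy_width * cth
        nc <- stats::rpois(1, config$canopy_density * ds * vol)
        if (nc > 0) {
          htop <- preset$canopy_height * stats::runif(1, 0.97, 1.03)
          add(cx + stats::runif(nc, -preset$canopy_width / 2,
                                preset$canopy_width / 2),
              stats::runif(nc, ylo, yhi),
              stats::runif(nc, preset$canopy_lower, htop), "canopy", r, p)
        }
      }
    }
    if (config$posts_per_row > 0) {
      ypost <- seq(0, config$row_length,
                   length.out = config$posts_per_row + 2)
      ypost <- ypost[-c(1, length(ypost))] + config$plant_spacing / 2
      for (yq in ypost) {
        npp <- max(4, round(40 * ds))
        a <- stats::runif(npp, 0, 2 * pi)
        add(cx + config$post_radius * cos(a), yq + config$post_radius * sin(a),
            stats::runif(npp, 0, config$post_height), "post", r, NA)
      }
    }
    row_info <- rbind(row_info, data.frame(
      row = r, preset = preset$name, center_x = cx,
      height = preset$canopy_height, width = preset$canopy_width,
      lower = preset$canopy_lower,
      n_plants = sum(present)))
  }
  if (!length(px)) stop("configuration generates no points")
  if (is.null(trunks))
    trunks <- data.frame(row = integer(0), plant = integer(0),
                         x = numeric(0), y = numeric(0))

  tz <- terrain_z(px, py)
  z <- tz + ph
  # trunk base elevation comes from the pre-rotation position; z is
  # unchanged by the horizontal rotation
  trunks$z <- terrain_z(trunks$x, trunks$y)
  # rotate scene so rows sit at `bearing` degrees from the y-axis
  ang <- -config$bearing * pi / 180
  center <- c(mean(range(px)), mean(range(py)))
  xy <- rotate_xy_mat(cbind(px, py), ang, center)
  txy <- rotate_xy_mat(as.matrix(trunks[, c("x", "y")]), ang, center)
  trunks$x <- txy[, 1]; trunks$y <- txy[, 2]

  # noise
  n <- length(px)
  xn <- xy[, 1] + stats::rnorm(n, 0, config$noise_sd)
  yn <- xy[, 2] + stats::rnorm(n, 0, config$noise_sd)
  zn <- z + stats::rnorm(n, 0, config$noise_sd)

  perm <- sample.int(n)
  cls_code <- .vy_class[pclass]
  cloud <- point_cloud(cbind(xn, yn, zn)[perm, , drop = FALSE],
                       attrs = list(class = unname(cls_code[perm]),
                                    row_id = ifelse(is.na(prow[perm]), -1L,
                                                    prow[perm])))
  labels <- tibble::tibble(class = pclass[perm],
                           row = prow[perm], plant = pplant[perm],
                           terrain_z = tz[perm], height = ph[perm])
  structure(list(cloud = cloud,
                 truth = list(labels = labels,
                              trunks = tibble::as_tibble(trunks),
                              rows = tibble::as_tibble(row_info),
                              terrain = list(slope = config$slope,
                                             aspect = config$aspect),
                              config = config)),
            class = "vineyard")
}

#' @export
print.vineyard <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<vineyard> %d rows (%s) | %d points | %d trunks | bearing %.0f deg, slope %.0f deg\n",
              cfg$n_rows, paste(unique(cfg$presets), collapse = "+"),
              n_points(x$cloud), nrow(x$truth$trunks), cfg$bearing,
              cfg$slope))
  invisible(x)
}
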