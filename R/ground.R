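#' Parameters of the cloth-simulation ground filter
#'
#' @param gr cloth grid resolution in meters (horizontal spacing of the
#'   simulated cloth particles). Default 0.3 m.
#' @param dt distance threshold in meters: a point is classified as ground
#'   when its vertical distance to the settled cloth is at most `dt`.
#'   Default 0.3 m.
#' @param iterations maximum number of simulation steps.
#' @param rigidness cloth stiffness class (number of internal-constraint
#'   passes per step); larger values give a flatter cloth.
#' @return an object of class `ground_filter_params`.
#' @export
ground_filter_params <- function(gr = 0.3, dt = 0.3, iterations = 500L,
                                 rigidness = 2L) {
  stopifnot(gr > 0, dt > 0, iterations >= 1, rigidness >= 1)
  structure(list(gr = gr, dt = dt, iterations = as.integer(iterations),
                 rigidness = as.integer(rigidness)),
            class = "ground_filter_params")
}

#' Separate ground from vegetation by cloth simulation
#'
#' Re-implementation of cloth-simulation filtering (CSF): the cloud is
#' inverted in z, a particle grid of spacing `gr` is draped onto the
#' inverted surface under gravity with internal stiffness constraints, and
#' each point is classified as ground when its vertical distance to the
#' settled cloth is at most `dt`. The scheme is robust on sloped terrain,
#' which is why it is the separation step of choice for hillside vineyards.
#'
#' @param cloud a `point_cloud` with at least 4 points spanning a
#'   nondegenerate horizontal extent.
#' @param params a [ground_filter_params()] object.
#' @return a list of class `ground_separation` with elements `ground` and
#'   `plant` (the two `point_cloud` partitions), `ground_idx` / `plant_idx`
#'   (indices into the input), and `cloth` (the settled terrain grid, an
#'   internal surface reusable by [build_terrain_model()]).
#' @export
csf_ground_filter <- function(cloud, params = ground_filter_params()) {
  n <- n_points(cloud)
  if (n < 4) stop("insufficient points for terrain simulation")
  gr <- params$gr
  x <- cloud$coords[, 1]; y <- cloud$coords[, 2]; zi <- -cloud$coords[, 3]
  if (diff(range(x)) <= 0 && diff(range(y)) <= 0)
    stop("cloud has a degenerate horizontal extent")

  xs <- seq(min(x) - gr, max(x) + gr, by = gr)
  ys <- seq(min(y) - gr, max(y) + gr, by = gr)
  nx <- length(xs); ny <- length(ys)
  ix <- pmin(pmax(round((x - xs[1]) / gr) + 1, 1), nx)
  iy <- pmin(pmax(round((y - ys[1]) / gr) + 1, 1), ny)

  # highest inverted point near each particle = terrain in the inverted frame
  hit <- matrix(-Inf, nx, ny)
  agg <- data.table::data.table(ix = ix, iy = iy, zi = zi)
  agg <- agg[, list(m = max(zi)), by = c("ix", "iy")]
  hit[cbind(agg$ix, agg$iy)] <- agg$m
  hit <- fill_grid(hit, statistic = "max")

  z <- matrix(max(hit) + 1, nx, ny)   # cloth starts above the surface
  zprev <- z
  movable <- matrix(TRUE, nx, ny)
  grav <- 0.12                         # gravity displacement per step, m
  for (it in seq_len(params$iterations)) {
    zref <- z
    znew <- z + (z - zprev) * 0.99 - grav
    znew[!movable] <- z[!movable]
    zprev <- z; z <- znew
    pin <- movable & (z < hit)
    if (any(pin)) {
      z[pin] <- hit[pin]; zprev[pin] <- z[pin]; movable[pin] <- FALSE
    }
    for (b in seq_len(params$rigidness)) {
      nav <- neighbor_mean(z)
      z[movable] <- z[movable] + 0.5 * (nav[movable] - z[movable])
      pin <- movable & (z < hit)
      if (any(pin)) {
        z[pin] <- hit[pin]; zprev[pin] <- z[pin]; movable[pin] <- FALSE
      }
    }
    if (max(abs(z - zref)) < 1e-4) break
  }

  cloth_at <- interp2_grid(xs, ys, z, x, y)
  is_ground <- (cloth_at - zi) <= params$dt
  structure(list(
    ground = pc_subset(cloud, which(is_ground)),
    plant = pc_subset(cloud, which(!is_ground)),
    ground_idx = which(is_ground),
    plant_idx = which(!is_ground),
    cloth = list(xs = xs, ys = ys, z = -z),   # back in the original frame
    params = params), class = "ground_separation")
}

#' @export
print.ground_separation <- function(x, ...) {
  cat(sprintf("<ground_separation> %d ground / %d plant points (GR %.2f m, DT %.2f m)\n",
              length(x$ground_idx), length(x$plant_idx),
              x$params$gr, x$params$dt))
  invisible(x)
}

# mean of the available 4-neighbours of every grid node
neighbor_mean <- function(z) {
  nx <- nrow(z); ny <- ncol(z)
  s <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  s[-1, ] <- s[-1, ] + z[-nx, ]; cnt[-1, ] <- cnt[-1, ] + 1
  s[-nx, ] <- s[-nx, ] + z[-1, ]; cnt[-nx, ] <- cnt[-nx, ] + 1
  s[, -1] <- s[, -1] + z[, -ny]; cnt[, -1] <- cnt[, -1] + 1
  s[, -ny] <- s[, -ny] + z[, -1]; cnt[, -ny] <- cnt[, -ny] + 1
  s / cnt
}

# replace non-finite cells by values dilated from filled neighbours
# (8-neighbourhood, repeated until full) -- a nearest-neighbour style fill
fill_grid <- function(z, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  if (all(is.finite(z))) return(z)
  if (!any(is.finite(z))) stop("grid has no occupied cells")
  nx <- nrow(z); ny <- ncol(z)
  for (pass in seq_len(nx + ny)) {
    empty <- !is.finite(z)
    if (!any(empty)) break
    zf <- z; zf[empty] <- NA
    shifts <- list(
      rbind(zf[-1, , drop = FALSE], NA), rbind(NA, zf[-nx, , drop = FALSE]),
      cbind(zf[, -1, drop = FALSE], NA), cbind(NA, zf[, -ny, drop = FALSE]))
    stack <- array(unlist(shifts), dim = c(nx, ny, 4))
    filled <- if (statistic == "max")
      suppressWarnings(apply(stack, c(1, 2), max, na.rm = TRUE))
    else
      suppressWarnings(apply(stack, c(1, 2), mean, na.rm = TRUE))
    take <- empty & is.finite(filled)
    z[take] <- filled[take]
  }
  z
}

# bilinear interpolation on a regular grid with clamping at the borders;
# attr "clamped" reports whether any query fell outside the grid
interp2_grid <- function(xs, ys, z, qx, qy) {
  nx <- length(xs); ny <- length(ys)
  fx <- (qx - xs[1]) / (xs[2] - xs[1])
  fy <- (qy - ys[1]) / (ys[2] - ys[1])
  clamped <- any(fx < 0 | fx > nx - 1 | fy < 0 | fy > ny - 1)
  fx <- pmin(pmax(fx, 0), nx - 1); fy <- pmin(pmax(fy, 0), ny - 1)
  i0 <- pmin(floor(fx) + 1, nx - 1); j0 <- pmin(floor(fy) + 1, ny - 1)
  tx <- fx - (i0 - 1); ty <- fy - (j0 - 1)
  v <- z[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
       z[cbind(i0 + 1, j0)] * tx * (1 - ty) +
       z[cbind(i0, j0 + 1)] * (1 - tx) * ty +
       z[cbind(i0 + 1, j0 + 1)] * tx * ty
  attr(v, "clamped") <- clamped
  v
}

#' Build a terrain elevation model from ground points
#'
#' Rasterizes the ground cloud onto a regular horizontal grid; the
#' elevation of each cell is a robust low quantile (5th percentile) of its
#' member points, which resists residual vegetation returns mislabeled as
#' ground. Empty cells are filled from their nearest occupied neighbours,
#' and queries interpolate bilinearly between cell centers.
#'
#' @param ground a nonempty `point_cloud` of ground points.
#' @param cell_size grid cell size in meters (default 0.3, matching the
#'   cloth resolution of [csf_ground_filter()]).
#' @param probs quantile used for the per-cell elevation.
#' @return an object of class `terrain_model`.
#' @export
build_terrain_model <- function(ground, cell_size = 0.3, probs = 0.05) {
  if (n_points(ground) == 0) stop("cannot build a terrain model without ground points")
  x <- ground$coords[, 1]; y <- ground$coords[, 2]; z <- ground$coords[, 3]
  xs <- seq(min(x) - cell_size / 2, max(x) + cell_size / 2, by = cell_size)
  ys <- seq(min(y) - cell_size / 2, max(y) + cell_size / 2, by = cell_size)
  if (length(xs) < 2) xs <- c(xs, xs + cell_size)
  if (length(ys) < 2) ys <- c(ys, ys + cell_size)
  ix <- pmin(pmax(round((x - xs[1]) / cell_size) + 1, 1), length(xs))
  iy <- pmin(pmax(round((y - ys[1]) / cell_size) + 1, 1), length(ys))
  zm <- matrix(-Inf, length(xs), length(ys))   # -Inf marks empty cells
  agg <- data.table::data.table(ix = ix, iy = iy, z = z)
  agg <- agg[, list(e = stats::quantile(z, probs, names = FALSE)),
             by = c("ix", "iy")]
  zm[cbind(agg$ix, agg$iy)] <- agg$e
  zm <- fill_grid(zm, statistic = "mean")
  structure(list(xs = xs, ys = ys, z = zm, cell = cell_size,
                 interpolation = "bilinear"), class = "terrain_model")
}

#' Query terrain elevation
#' @param terrain a `terrain_model`.
#' @param x,y query coordinates, meters (vectors of equal length).
#' @return elevations in meters; queries outside the modeled extent are
#'   clamped to the nearest covered location.
#' @export
terrain_elevation <- function(terrain, x, y) {
  v <- interp2_grid(terrain$xs, terrain$ys, terrain$z, x, y)
  as.vector(unname(unclass(v)))[seq_along(x)]
}

#' Height-normalize a plant cloud
#'
#' Replaces each point's elevation with its height above the local terrain
#' surface (`z - terrain(x, y)`), converting ellipsoidal or absolute
#' heights into plant heights. x and y are unchanged.
#'
#' @param plant a `point_cloud` of vegetation points.
#' @param terrain a `terrain_model` covering the plant extent.
#' @return the height-normalized `point_cloud`.
#' @export
normalize_heights <- function(plant, terrain) {
  if (n_points(plant) == 0) return(plant)
  e <- interp2_grid(terrain$xs, terrain$ys, terrain$z,
                    plant$coords[, 1], plant$coords[, 2])
  if (isTRUE(attr(e, "clamped")))
    warning("some plant points fall outside the terrain model; elevations were clamped to the nearest covered location")
  m <- plant$coords
  m[, 3] <- m[, 3] - as.vector(unname(unclass(e)))[seq_len(nrow(m))]
  point_cloud(m, plant$attrs, plant$origin)
}
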