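#' Density-based clustering parameters
#'
#' @param eps neighborhood radius in meters. The row-segmentation default
#'   of 0.35 m matches the average inter-point distance of a plant cloud
#'   downsampled at 0.1 m; trunk-candidate clustering uses 0.10 m.
#' @param min_points minimum number of points (query point included)
#'   within `eps` for a core point. Defaults: 40 for rows, 5 for trunks.
#' @return an object of class `cluster_params`.
#' @export
cluster_params <- function(eps = 0.35, min_points = 40L) {
  stopifnot(eps > 0, min_points >= 1)
  structure(list(eps = eps, min_points = as.integer(min_points)),
            class = "cluster_params")
}

#' Centroid-merge parameters for over-segmented rows
#' @param distance centroid distance threshold d in meters along the
#'   cross-row (x) axis; clusters closer than `d` are merged. Default 1 m.
#' @return an object of class `merge_params`.
#' @export
merge_params <- function(distance = 1.0) {
  stopifnot(distance > 0)
  structure(list(distance = distance), class = "merge_params")
}

#' DBSCAN clustering
#'
#' Standard DBSCAN with Euclidean distance: a point is a core point when at
#' least `min_points` points (itself included) lie within `eps`; clusters
#' are the maximal density-connected sets, border points join a reachable
#' core's cluster, and everything else is noise. Backed by a uniform-grid
#' neighborhood index so large clouds stay tractable.
#'
#' @param points N x D numeric matrix, D in \{2, 3\}.
#' @param params a [cluster_params()] object.
#' @return integer labels of length N: 0..K-1 for clusters (numbered in
#'   order of first appearance), -1 for noise.
#' @export
dbscan <- function(points, params = cluster_params()) {
  points <- as.matrix(points)
  if (nrow(points) == 0) return(integer(0))
  if (!ncol(points) %in% c(2, 3)) stop("`points` must be N x 2 or N x 3")
  storage.mode(points) <- "double"
  .dbscan_cpp(points, params$eps, params$min_points)
}

#' Estimate the common row orientation
#'
#' Fits a principal-axis (total-least-squares) line to every cluster and
#' combines the per-cluster directions into a single axial mean weighted by
#' point count. Directions are axial -- a row has no head or tail -- so the
#' average is taken on the doubled angle. The result is the rotation angle
#' theta that maps the common row direction onto the y-axis.
#'
#' @param points2d M x 2 matrix of horizontal coordinates.
#' @param labels cluster labels as returned by [dbscan()]; noise (-1) is
#'   ignored.
#' @return theta in radians, in (-pi/2, pi/2].
#' @export
estimate_row_orientation <- function(points2d, labels) {
  points2d <- as.matrix(points2d)
  ids <- sort(unique(labels[labels >= 0]))
  ang <- numeric(0); w <- numeric(0)
  for (id in ids) {
    idx <- which(labels == id)
    if (length(idx) < 2) next
    cc <- stats::cov(points2d[idx, , drop = FALSE])
    v <- eigen(cc, symmetric = TRUE)$vectors[, 1]
    ang <- c(ang, atan2(v[1], v[2]))  # angle of the row axis from +y
    w <- c(w, length(idx))
  }
  if (!length(ang)) stop("cannot estimate orientation")
  theta <- 0.5 * atan2(sum(w * sin(2 * ang)), sum(w * cos(2 * ang)))
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  theta
}

#' Merge over-segmented row clusters by centroid proximity
#'
#' After rotation the rows run along y, so clusters belonging to the same
#' physical row (split by canopy gaps, missing plants, or a separately
#' clustered post) share the same cross-row position. Clusters whose
#' centroids differ by less than `d` in |delta x| are single-linkage
#' grouped into one row; merged rows are renumbered by ascending mean x.
#'
#' @param points2d M x 2 matrix of rotated horizontal coordinates (rows
#'   parallel to the y-axis).
#' @param labels cluster labels (-1 = noise, ignored).
#' @param params a [merge_params()] object.
#' @return integer labels of length M with merged rows 0..R-1, noise -1.
#' @export
merge_row_clusters <- function(points2d, labels, params = merge_params()) {
  points2d <- as.matrix(points2d)
  ids <- sort(unique(labels[labels >= 0]))
  if (!length(ids)) return(labels)
  cx <- vapply(ids, function(id) mean(points2d[labels == id, 1]), 0)
  ord <- order(cx)
  # single linkage in 1D: chain clusters while consecutive gaps are < d
  group <- integer(length(ids)); g <- 0L
  for (k in seq_along(ord)) {
    if (k > 1 && (cx[ord[k]] - cx[ord[k - 1]]) >= params$distance) g <- g + 1L
    group[ord[k]] <- g
  }
  out <- labels
  keep <- labels >= 0
  out[keep] <- group[match(labels[keep], ids)]
  out
}

#' Segment a plant cloud into individual vine rows
#'
#' The full row-segmentation pipeline: voxel downsampling, 2D DBSCAN on the
#' horizontal projection, row-orientation estimation, rotation of the cloud
#' so rows run along y, centroid merging of over-segmented clusters, and
#' propagation of the row labels from the downsampled representatives back
#' to every full-resolution point. Full-resolution points whose voxel
#' representative ended up as noise join the nearest row within `2 * eps`,
#' otherwise they stay unassigned.
#'
#' @param plant a nonempty `point_cloud` (typically the height-normalized
#'   plant partition).
#' @param cluster a [cluster_params()] object (defaults eps 0.35 m, 40).
#' @param merge a [merge_params()] object (default 1 m).
#' @param voxel downsampling voxel edge in meters (default 0.1).
#' @return an object of class `row_model`: the orientation `theta`
#'   (radians), the rotation `pivot`, per-point `labels` (1..K, NA =
#'   unassigned), and `rows`, a list with per-row plant indices, 3D
#'   bounding box in the rotated frame, and centroid.
#' @export
segment_rows <- function(plant, cluster = cluster_params(),
                         merge = merge_params(), voxel = 0.1) {
  if (n_points(plant) == 0) stop("cannot segment an empty plant cloud")
  ds <- voxel_downsample(plant, voxel)
  vidx <- attr(ds, "voxel_index")
  lab0 <- dbscan(ds$coords[, 1:2, drop = FALSE], cluster)
  if (!any(lab0 >= 0))
    stop("no rows detected; check eps/min_points against point density")
  theta <- estimate_row_orientation(ds$coords[, 1:2, drop = FALSE], lab0)
  pivot <- colMeans(plant$coords[, 1:2, drop = FALSE])
  ds_rot <- rotate_xy_mat(ds$coords[, 1:2, drop = FALSE], theta, pivot)
  merged <- merge_row_clusters(ds_rot, lab0, merge)

  full_rot <- rotate_xy_mat(plant$coords[, 1:2, drop = FALSE], theta, pivot)
  full_lab <- merged[vidx]
  # points whose voxel representative was noise join the nearest row
  # within 2*eps. A row is its set of assigned points, so attachment is
  # iterated to a fixpoint: contiguous structures (canopy fragments below
  # the core threshold, trunk tops poking out of a gap) chain onto their
  # row instead of being orphaned by the sparsity of the downsampled
  # representatives
  repeat {
    miss <- which(full_lab < 0)
    if (!length(miss)) break
    ok <- which(full_lab >= 0)
    res <- .nearest_label_cpp(full_rot[miss, , drop = FALSE],
                              full_rot[ok, , drop = FALSE],
                              as.integer(full_lab[ok]), 2 * cluster$eps)
    if (all(res < 0)) break
    full_lab[miss] <- res
  }
  n_unassigned <- sum(full_lab < 0)
  if (n_unassigned > 0)
    message(sprintf("%d plant points could not be attached to a row", n_unassigned))
  full_lab <- ifelse(full_lab < 0, NA_integer_, full_lab + 1L)

  zfull <- plant$coords[, 3]
  rows <- lapply(sort(unique(full_lab[!is.na(full_lab)])), function(id) {
    idx <- which(full_lab == id)
    rx <- range(full_rot[idx, 1]); ry <- range(full_rot[idx, 2])
    rz <- range(zfull[idx])
    list(id = id, plant_idx = idx,
         plant_box = bbox3d(c(rx[1], ry[1], rz[1]), c(rx[2], ry[2], rz[2])),
         ground_idx = NULL, ground_box = NULL,
         centroid = c(mean(full_rot[idx, 1]), mean(full_rot[idx, 2]),
                      mean(zfull[idx])))
  })
  structure(list(theta = theta, pivot = pivot, labels = full_lab,
                 rows = rows, n_rows = length(rows),
                 n_unassigned = n_unassigned,
                 cluster = cluster, merge = merge, voxel = voxel),
            class = "row_model")
}

#' @export
print.row_model <- function(x, ...) {
  cat(sprintf("<row_model> %d rows | theta %.2f deg | %d unassigned points\n",
              x$n_rows, x$theta * 180 / pi, x$n_unassigned))
  for (r in x$rows)
    cat(sprintf("  row %d: %d plant / %s ground points\n", r$id,
                length(r$plant_idx),
                if (is.null(r$ground_idx)) "-" else length(r$ground_idx)))
  invisible(x)
}

#' Carry a row segmentation onto the ground cloud
#'
#' Rotates the ground cloud by the model's orientation and assigns ground
#' points to rows through 3D bounding boxes: each row's box takes the x and
#' y extents of its plant points (rotated frame) and the z extent of the
#' whole ground cloud. Points falling in no box stay unassigned.
#'
#' @param ground a `point_cloud` of ground points.
#' @param model a `row_model` from [segment_rows()].
#' @return the model with `ground_idx` / `ground_box` filled per row and a
#'   `ground_labels` vector (1..K, NA = unassigned) aligned to `ground`.
#' @export
segment_ground_rows <- function(ground, model) {
  g_rot <- rotate_xy_mat(ground$coords[, 1:2, drop = FALSE],
                         model$theta, model$pivot)
  gz <- ground$coords[, 3]
  zr <- if (length(gz)) range(gz) else c(0, 0)
  labels <- rep(NA_integer_, n_points(ground))
  for (k in seq_along(model$rows)) {
    row <- model$rows[[k]]
    box <- bbox3d(c(row$plant_box$min[1:2], zr[1]),
                  c(row$plant_box$max[1:2], zr[2]))
    inside <- which(is.na(labels) &
                    g_rot[, 1] >= box$min[1] & g_rot[, 1] <= box$max[1] &
                    g_rot[, 2] >= box$min[2] & g_rot[, 2] <= box$max[2] &
                    gz >= box$min[3] & gz <= box$max[3])
    model$rows[[k]]$ground_idx <- inside
    model$rows[[k]]$ground_box <- box
    labels[inside] <- row$id
  }
  model$ground_labels <- labels
  model
}
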