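#' Parameters for local geometric feature computation
#'
#' @param radius neighborhood radius R in meters for the covariance
#'   analysis. The default 0.25 m captures the approximate diameter of a
#'   vine trunk together with the surrounding ground.
#' @param voxel downsampling voxel edge applied before the feature
#'   computation (default 0.05 m), which stabilizes the neighborhood
#'   density.
#' @return an object of class `feature_params`.
#' @export
feature_params <- function(radius = 0.25, voxel = 0.05) {
  stopifnot(radius > 0, voxel > 0)
  structure(list(radius = radius, voxel = voxel), class = "feature_params")
}

#' Per-point sphericity from local covariance eigenvalues
#'
#' For every point of the (downsampled) cloud, the covariance matrix of all
#' points within radius R (query point included, 1/n normalization) is
#' eigendecomposed with eigenvalues sorted lambda1 >= lambda2 >= lambda3 >=
#' 0, and the sphericity S = lambda3 / lambda1 is computed. Near-planar
#' ground gives S close to 0, while a trunk base rising out of the ground
#' produces genuinely 3D local spread and a high S -- the signal exploited
#' by [detect_trunks()]. Points with fewer than 3 neighbors (no
#' nondegenerate covariance) get S = 0.
#'
#' @param cloud a `point_cloud`, typically a segmented ground row.
#' @param params a [feature_params()] object.
#' @return an object of class `sphericity_field`: the downsampled `cloud`
#'   carrying a `sphericity` attribute, plus the `eigenvalues` matrix
#'   (N x 3, descending) and the parameters used.
#' @export
compute_sphericity <- function(cloud, params = feature_params()) {
  ds <- voxel_downsample(cloud, params$voxel)
  m <- .sphericity_cpp(ds$coords, params$radius)
  ds <- pc_set_attr(ds, "sphericity", m[, 4])
  structure(list(cloud = ds, eigenvalues = m[, 1:3, drop = FALSE],
                 params = params),
            class = "sphericity_field")
}

#' @export
print.sphericity_field <- function(x, ...) {
  s <- pc_attr(x$cloud, "sphericity")
  cat(sprintf("<sphericity_field> %d points | S in [%.3f, %.3f], mean %.3f (R %.2f m)\n",
              n_points(x$cloud), min(s), max(s), mean(s), x$params$radius))
  invisible(x)
}

#' Otsu's histogram threshold
#'
#' Bins the values into `bins` equal-width bins over their observed range
#' and returns the bin edge that maximizes the between-class variance
#' w0 * w1 * (mu0 - mu1)^2 of the induced two-class split. Ties break
#' toward the lower threshold.
#'
#' @param values numeric vector (at least two distinct values).
#' @param bins number of histogram bins (default 256).
#' @return the threshold (a bin edge).
#' @export
otsu_threshold <- function(values, bins = 256L) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) stop("degenerate histogram")
  bins <- as.integer(bins)
  br <- seq(min(v), max(v), length.out = bins + 1)
  idx <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(idx, bins)
  mids <- (br[-1] + br[-(bins + 1)]) / 2
  W <- cumsum(cnt)
  M <- cumsum(cnt * mids)
  tot <- W[bins]; mtot <- M[bins]
  k <- seq_len(bins - 1)
  w0 <- W[k]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, bins - 1)
  mu0 <- M[k][valid] / w0[valid]
  mu1 <- (mtot - M[k][valid]) / w1[valid]
  sb[valid] <- (w0[valid] / tot) * (w1[valid] / tot) * (mu0 - mu1)^2
  br[which.max(sb) + 1]   # which.max takes the first (lowest) maximizer
}

#' Detect trunk positions in a segmented ground row
#'
#' Three steps: (1) candidate points are those whose sphericity exceeds the
#' Otsu threshold computed over the row's own sphericity values; (2) the
#' candidates are clustered in 3D by DBSCAN (defaults eps 0.10 m,
#' min_points 5) and noise is discarded; (3) each cluster contributes one
#' trunk position, the arithmetic 3D centroid of its points.
#'
#' @param row_ground a nonempty `point_cloud`, one row of the ground cloud.
#' @param feat a [feature_params()] object.
#' @param cluster a [cluster_params()] object for candidate clustering.
#' @param otsu_bins histogram bins for the threshold.
#' @return an object of class `trunk_set`: `positions` (K x 3 matrix in the
#'   frame of the input cloud), `members` (list of point indices into the
#'   downsampled feature cloud), `threshold`, `field` (the
#'   `sphericity_field`). An empty set (K = 0) is a valid result when no
#'   point clears the threshold.
#' @export
detect_trunks <- function(row_ground, feat = feature_params(),
                          cluster = cluster_params(eps = 0.10, min_points = 5L),
                          otsu_bins = 256L) {
  if (n_points(row_ground) == 0) stop("cannot detect trunks in an empty cloud")
  field <- compute_sphericity(row_ground, feat)
  s <- pc_attr(field$cloud, "sphericity")
  empty <- function(thr) {
    message("no trunk candidates above the sphericity threshold")
    structure(list(positions = matrix(numeric(0), ncol = 3,
                                      dimnames = list(NULL, c("x", "y", "z"))),
                   members = list(), threshold = thr, field = field),
              class = "trunk_set")
  }
  if (length(unique(s)) < 2) return(empty(NA_real_))
  thr <- otsu_threshold(s, otsu_bins)
  cand <- which(s > thr)
  if (!length(cand)) return(empty(thr))
  lab <- dbscan(field$cloud$coords[cand, , drop = FALSE], cluster)
  ids <- sort(unique(lab[lab >= 0]))
  if (!length(ids)) return(empty(thr))
  members <- lapply(ids, function(id) cand[lab == id])
  pos <- t(vapply(members, function(idx)
    colMeans(field$cloud$coords[idx, , drop = FALSE]), numeric(3)))
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, members = members, threshold = thr,
                 field = field),
            class = "trunk_set")
}

#' @export
print.trunk_set <- function(x, ...) {
  cat(sprintf("<trunk_set> %d trunks (sphericity threshold %.3f)\n",
              nrow(x$positions), x$threshold))
  invisible(x)
}
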