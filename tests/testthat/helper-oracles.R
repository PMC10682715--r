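# Independent brute-force oracles used to validate the grid-accelerated
# implementations. All are deliberately naive O(N^2)-or-worse versions.

# DBSCAN by explicit density-connectivity over the full distance matrix
brute_dbscan <- function(x, eps, min_pts) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  core <- rowSums(D <= eps) >= min_pts
  lab <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != -1L) next
    lab[i] <- cl
    repeat {
      grew <- FALSE
      for (j in which(lab == cl & core)) {
        nb <- which(D[j, ] <= eps & lab == -1L)
        if (length(nb)) { lab[nb] <- cl; grew <- TRUE }
      }
      if (!grew) break
    }
    cl <- cl + 1L
  }
  lab
}

# two labelings describe the same partition (noise must coincide exactly)
same_partition <- function(a, b) {
  if (!all((a == -1) == (b == -1))) return(FALSE)
  keep <- a != -1
  if (!any(keep)) return(TRUE)
  ta <- table(a[keep], b[keep])
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# Otsu by exhaustive search over every internal bin edge
otsu_exhaustive <- function(v, bins = 256L) {
  br <- seq(min(v), max(v), length.out = bins + 1)
  idx <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  best <- -Inf; best_thr <- NA_real_
  for (k in seq_len(bins - 1)) {
    lo <- idx <= k
    n0 <- sum(lo); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    mids <- (br[-1] + br[-(bins + 1)]) / 2
    mu0 <- sum(mids[idx[lo]]) / n0
    mu1 <- sum(mids[idx[!lo]]) / n1
    sb <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (sb > best + 1e-15) { best <- sb; best_thr <- br[k + 1] }
  }
  best_thr
}

# mean k-NN distance per point, straight from the distance matrix
brute_knn_meandist <- function(x, k) {
  D <- as.matrix(stats::dist(x))
  vapply(seq_len(nrow(x)), function(i) mean(sort(D[i, -i])[seq_len(k)]), 0)
}

# convex-hull volume by brute-force face enumeration (small n only):
# every triple of points whose plane has all other points on one side is a
# hull face; the volume is the sum of signed tetrahedra to the centroid
brute_hull_volume <- function(x) {
  n <- nrow(x)
  stopifnot(n >= 4, n <= 60)
  ctr <- colMeans(x)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- x[i, ]; b <- x[j, ]; c <- x[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    s <- as.vector((x - matrix(a, n, 3, byrow = TRUE)) %*% nrm)
    tol <- 1e-12 * max(abs(s))
    if (all(s <= tol) || all(s >= -tol))
      vol <- vol + abs(det(rbind(a - ctr, b - ctr, c - ctr))) / 6
  }
  vol
}

# optimal one-to-one matching size within a radius, by exhaustive
# assignment enumeration (tiny instances only)
brute_best_matching <- function(est, ref, radius) {
  K <- nrow(est); M <- nrow(ref)
  if (K == 0 || M == 0) return(0L)
  ok <- outer(seq_len(K), seq_len(M), function(i, j)
    sqrt((est[i, 1] - ref[j, 1])^2 + (est[i, 2] - ref[j, 2])^2) <= radius)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (K - i + 1) <= best) return()
    if (i > K) { best <<- max(best, count); return() }
    recurse(i + 1, used, count)
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(M), 0L)
  best
}
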