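# Convex-hull hypervolumes in 1-3 dimensions.
#
# Trait-space niche volumes only ever need low dimensionality here: hulls are
# computed after projection onto leading pooled principal axes (see
# functional_richness), so an exact 1-3D implementation suffices.  Degenerate
# (affinely dependent) point sets have zero volume by contract.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# affine rank of a point cloud, with a scale-relative tolerance
affine_rank <- function(P, tol = 1e-10) {
  P <- as_numeric_matrix(P)
  if (nrow(P) < 2L) return(0L)
  C <- sweep(P, 2L, colMeans(P))
  d <- svd(C, nu = 0L, nv = 0L)$d
  sum(d > tol * max(d[1L], 1))
}

#' Convex hull volume of a point cloud
#'
#' Exact hypervolume of the convex hull of a set of points in 1, 2 or 3
#' dimensions (length, area, volume respectively).  Affinely degenerate
#' configurations (e.g. collinear points in 2-D) return 0 rather than
#' erroring, which is the convention needed when community richness barely
#' exceeds the trait-space dimension.
#'
#' @param points numeric matrix (rows = points, columns = coordinates) with
#'   1 to 3 columns; a vector is treated as one-dimensional points.
#' @return a single non-negative number.
#' @examples
#' convex_hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) # unit square
#' @export
convex_hull_volume <- function(points) {
  P <- as_numeric_matrix(points, "points")
  d <- ncol(P)
  if (d > 3L)
    stop_fd("hull volume implemented for 1-3 dimensions, got %d", d,
            class = "unsupported_dimension")
  if (nrow(P) <= d) return(0)
  if (affine_rank(P) < d) return(0)
  switch(d, hull_volume_1d(P), hull_volume_2d(P), hull_volume_3d(P))
}

hull_volume_1d <- function(P) diff(range(P[, 1L]))

hull_volume_2d <- function(P) {
  idx <- grDevices::chull(P[, 1L], P[, 2L])
  H <- P[idx, , drop = FALSE]
  n <- nrow(H)
  j <- c(2:n, 1L)
  abs(sum(H[, 1L] * H[j, 2L] - H[j, 1L] * H[, 2L])) / 2
}

# Incremental (beneath-beyond) 3-D hull.  Facets are stored as index
# triples; orientation is irrelevant because visibility and the final
# volume are both computed relative to a fixed interior point.
hull_volume_3d <- function(P) {
  n <- nrow(P)
  scale <- max(apply(P, 2L, function(x) diff(range(x))), 1e-300)
  eps <- 1e-12 * scale

  i0 <- which.min(P[, 1L])
  d2 <- rowSums((P - matrix(P[i0, ], n, 3L, byrow = TRUE))^2)
  i1 <- which.max(d2)
  v1 <- P[i1, ] - P[i0, ]
  area2 <- vapply(seq_len(n), function(i) {
    sum(cross3(v1, P[i, ] - P[i0, ])^2)
  }, numeric(1))
  i2 <- which.max(area2)
  nrm <- cross3(v1, P[i2, ] - P[i0, ])
  hgt <- abs(as.vector((P - matrix(P[i0, ], n, 3L, byrow = TRUE)) %*% nrm)) /
    sqrt(sum(nrm^2))
  i3 <- which.max(hgt)
  if (hgt[i3] <= eps) return(0)

  tet <- c(i0, i1, i2, i3)
  interior <- colMeans(P[tet, ])
  faces <- rbind(c(i0, i1, i2), c(i0, i1, i3), c(i0, i2, i3), c(i1, i2, i3))

  outward_normal <- function(f) {
    nrm <- cross3(P[f[2L], ] - P[f[1L], ], P[f[3L], ] - P[f[1L], ])
    if (sum(nrm * (P[f[1L], ] - interior)) < 0) nrm <- -nrm
    nrm
  }

  for (p in setdiff(seq_len(n), tet)) {
    nf <- nrow(faces)
    vis <- logical(nf)
    for (k in seq_len(nf)) {
      f <- faces[k, ]
      nrm <- outward_normal(f)
      vis[k] <- sum(nrm * (P[p, ] - P[f[1L], ])) > eps * sqrt(sum(nrm^2))
    }
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    edges <- rbind(visf[, c(1L, 2L)], visf[, c(2L, 3L)], visf[, c(3L, 1L)])
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    cnt <- table(key)
    horizon <- edges[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
    faces <- rbind(faces, cbind(horizon, p))
  }

  vol <- 0
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    M <- rbind(P[f[1L], ] - interior, P[f[2L], ] - interior,
               P[f[3L], ] - interior)
    vol <- vol + abs(det(M)) / 6
  }
  vol
}
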