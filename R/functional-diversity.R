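# Trait-space functional diversity indices: convex-hull richness (FRic),
# minimum-spanning-tree evenness (FEve), dispersion around the weighted
# centroid (FDis) and Rao's quadratic entropy.  All indices operate on
# traits z-scored over the full species pool, so that Euclidean geometry is
# meaningful across traits with incommensurate units.

#' Standardize a species-by-trait matrix over the species pool
#'
#' Each trait column is centered and scaled to unit standard deviation over
#' the whole pool (never per community).  Applying the function to an
#' already standardized matrix is a no-op.
#'
#' @param traits numeric species x trait matrix (rownames = species ids).
#' @return the standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize_traits <- function(traits) {
  X <- as_numeric_matrix(traits, "traits")
  if (isTRUE(attr(traits, "standardized"))) return(traits)
  sds <- apply(X, 2L, stats::sd)
  bad <- which(!is.finite(sds) | sds <= 0)
  if (length(bad))
    stop_fd("zero-variance trait column(s): %s",
            paste(colnames(X)[bad] %||% bad, collapse = ", "),
            class = "degenerate_trait")
  Z <- scale(X, center = TRUE, scale = sds)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  dimnames(Z) <- dimnames(X)
  attr(Z, "standardized") <- TRUE
  Z
}

#' Pairwise Euclidean trait distances
#'
#' Full symmetric matrix of Euclidean dissimilarities
#' \eqn{d_{ij} = \sqrt{\sum_t (x_{tj} - x_{ti})^2}} between species in
#' (standardized) trait space.
#'
#' @param traits species x trait matrix, normally standardized first.
#' @return symmetric matrix with zero diagonal.
#' @export
euclidean_distances <- function(traits) {
  X <- as_numeric_matrix(traits, "traits")
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Minimum spanning tree of a distance matrix
#'
#' Prim's algorithm with deterministic tie-breaking: when several edges of
#' equal weight are eligible the lexicographically smallest vertex pair (in
#' input order) is chosen, so results are identical across platforms.
#'
#' @param dist symmetric distance matrix over S species (S >= 2).
#' @return matrix with columns `from`, `to` (indices into `dist`, from < to)
#'   and `weight`; S - 1 rows.
#' @export
minimum_spanning_tree <- function(dist) {
  D <- as_numeric_matrix(dist, "dist")
  S <- nrow(D)
  if (S < 2L)
    stop_fd("MST undefined for fewer than 2 species", class = "undefined_mst")
  in_tree <- logical(S)
  in_tree[1L] <- TRUE
  key <- D[1L, ]
  parent <- rep(1L, S)
  edges <- matrix(0, S - 1L, 3L,
                  dimnames = list(NULL, c("from", "to", "weight")))
  for (e in seq_len(S - 1L)) {
    best <- 0L
    for (v in seq_len(S)) {   # scan order breaks ties lexicographically
      if (in_tree[v]) next
      if (best == 0L || key[v] < key[best] ||
          (key[v] == key[best] &&
           (pmin(parent[v], v) < pmin(parent[best], best) ||
            (pmin(parent[v], v) == pmin(parent[best], best) &&
             pmax(parent[v], v) < pmax(parent[best], best)))))
        best <- v
    }
    in_tree[best] <- TRUE
    edges[e, ] <- c(min(parent[best], best), max(parent[best], best),
                    D[parent[best], best])
    upd <- !in_tree & D[best, ] < key
    parent[upd] <- best
    key[upd] <- D[best, upd]
  }
  edges
}

#' Functional richness as a fraction of a reference hull volume
#'
#' Ratio of the community's convex-hull volume in trait space to a
#' reference volume.  When `reference` is a point cloud (the pooled
#' standardized traits), both community and reference are first projected
#' onto the leading `min(S - 1, T, hull_dim)` principal axes of the
#' reference cloud, so that hulls are full-dimensional; `hull_dim` caps the
#' geometry at 3 dimensions where exact hull volumes are computed.
#'
#' @param points community species coordinates (rows) in standardized trait
#'   space.
#' @param reference either a positive reference volume (scalar) or the
#'   pooled coordinate matrix from which the reference hull is built.
#' @param hull_dim maximum hull dimensionality (default 3).
#' @return FRic in `[0, 1]` when the reference hull encloses the community.
#' @export
functional_richness <- function(points, reference, hull_dim = 3L) {
  P <- as_numeric_matrix(points, "points")
  if (nrow(P) < 2L) return(0)
  if (is.numeric(reference) && length(reference) == 1L) {
    if (reference <= 0)
      stop_fd("reference volume must be positive", class = "domain_error")
    return(convex_hull_volume(P) / reference)
  }
  R <- as_numeric_matrix(reference, "reference")
  if (ncol(R) != ncol(P))
    stop_fd("community and reference dimensionality differ",
            class = "dimension_error")
  m <- min(nrow(P) - 1L, ncol(P), hull_dim)
  if (m < 1L) return(0)
  if (m < ncol(P)) {
    C <- sweep(R, 2L, colMeans(R))
    ax <- svd(C, nu = 0L, nv = m)$v
    P <- P %*% ax
    R <- R %*% ax
  }
  ref_vol <- convex_hull_volume(R)
  if (ref_vol <= 0)
    stop_fd("degenerate reference hull (zero volume)", class = "domain_error")
  convex_hull_volume(P) / ref_vol
}

#' Functional evenness along the trait-space minimum spanning tree
#'
#' Branch evenness of abundance-weighted MST branch lengths:
#' \eqn{EW_l = d_{ij} / (P_i + P_j)}, \eqn{PEW_l = EW_l / \sum EW}, and
#' \eqn{FEve = (\sum_l \min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))}.
#' Bounded in `[0, 1]`; 1 means perfectly regular spacing and abundance.
#'
#' @param dist symmetric trait-distance matrix over the community species.
#' @param abundances relative abundances aligned with `dist` rows.
#' @return FEve, or `NA` for S < 3 (the normalizing denominator vanishes at
#'   S = 2).
#' @export
functional_evenness <- function(dist, abundances) {
  D <- as_numeric_matrix(dist, "dist")
  p <- as.numeric(abundances)
  S <- nrow(D)
  if (length(p) != S)
    stop_fd("abundance length (%d) != distance dimension (%d)",
            length(p), S, class = "dimension_error")
  if (S < 3L) return(NA_real_)
  mst <- minimum_spanning_tree(D)
  ew <- mst[, "weight"] / (p[mst[, "from"]] + p[mst[, "to"]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional dispersion
#'
#' Abundance-weighted mean Euclidean distance of species to the
#' abundance-weighted community centroid in standardized trait space.
#'
#' @param points community species coordinates (rows).
#' @param abundances non-negative weights, not all zero.
#' @return FDis >= 0 (0 for a single species).
#' @export
functional_dispersion <- function(points, abundances) {
  P <- as_numeric_matrix(points, "points")
  a <- as.numeric(abundances)
  if (length(a) != nrow(P))
    stop_fd("abundance length (%d) != number of species (%d)",
            length(a), nrow(P), class = "dimension_error")
  if (any(a < 0) || sum(a) <= 0)
    stop_fd("abundances must be non-negative and not all zero",
            class = "domain_error")
  w <- a / sum(a)
  centroid <- colSums(P * w)
  z <- sqrt(rowSums(sweep(P, 2L, centroid)^2))
  sum(w * z)
}

#' Rao's quadratic entropy
#'
#' Expected trait distance between two individuals drawn at random:
#' \eqn{Q = \sum_{i<j} d_{ij} p_i p_j}.  Abundances must already form a
#' probability vector; the function refuses to renormalize silently.
#'
#' @param dist symmetric trait-distance matrix.
#' @param abundances relative abundances summing to 1 (tolerance 1e-8).
#' @return Rao's Q >= 0.
#' @export
rao_quadratic_entropy <- function(dist, abundances) {
  D <- as_numeric_matrix(dist, "dist")
  p <- as.numeric(abundances)
  if (length(p) != nrow(D))
    stop_fd("abundance length (%d) != distance dimension (%d)",
            length(p), nrow(D), class = "dimension_error")
  if (abs(sum(p) - 1) > 1e-8)
    stop_fd("abundances must sum to 1 (got %.6f); renormalize explicitly",
            sum(p), class = "normalization_error")
  sum(D[upper.tri(D)] * (p %o% p)[upper.tri(D)])
}

#' All four functional diversity indices for one site
#'
#' Standardizes traits over the full species pool, restricts to species
#' with positive abundance at the site, and computes FRic (pooled-hull
#' reference), FEve, FDis and Rao's Q.  Degenerate contract for a
#' single-species community: FRic = FDis = RaoQ = 0 and FEve missing.
#'
#' @param dataset a list with `trait_matrix` and `abundance_table` (and
#'   optionally `biomass_table`) as produced by [generate_communities()] or
#'   [worked_example()].
#' @param site site identifier (rowname of the abundance table).
#' @param weighting `"abundance"` (relative abundance table, default) or
#'   `"biomass"` (per-site biomass shares).
#' @param hull_dim maximum hull dimensionality for FRic (default 3).
#' @return object of class `fd_result`: list with `site`, `s`, `fric`,
#'   `feve`, `fdis`, `raoq`.
#' @export
fd_suite <- function(dataset, site, weighting = c("abundance", "biomass"),
                     hull_dim = 3L) {
  weighting <- match.arg(weighting)
  A <- as_numeric_matrix(dataset$abundance_table, "abundance_table")
  if (!site %in% rownames(A))
    stop_fd("site '%s' not found in abundance table", site,
            class = "lookup_error")
  Z <- standardize_traits(dataset$trait_matrix)
  p <- A[site, ]
  if (weighting == "biomass") {
    B <- dataset$biomass_table
    b <- B[B$site == site, , drop = FALSE]
    bm <- tapply(b$biomass, b$species, mean)
    p <- rep(0, ncol(A)); names(p) <- colnames(A)
    p[names(bm)] <- bm / sum(bm)
  }
  keep <- which(p > 0)
  if (!length(keep))
    stop_fd("site '%s' has no species with positive abundance", site,
            class = "empty_community")
  missing_sp <- setdiff(colnames(A)[keep], rownames(Z))
  if (length(missing_sp))
    stop_fd("species absent from trait table: %s",
            paste(missing_sp, collapse = ", "), class = "lookup_error")
  pts <- Z[colnames(A)[keep], , drop = FALSE]
  pa <- p[keep] / sum(p[keep])
  S <- length(keep)
  if (S == 1L) {
    res <- list(site = site, s = 1L, fric = 0, feve = NA_real_,
                fdis = 0, raoq = 0)
  } else {
    D <- euclidean_distances(pts)
    res <- list(
      site = site, s = S,
      fric = functional_richness(pts, Z, hull_dim = hull_dim),
      feve = functional_evenness(D, pa),
      fdis = functional_dispersion(pts, pa),
      raoq = rao_quadratic_entropy(D, pa))
  }
  structure(res, class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("Functional diversity for site '%s' (S = %d)\n", x$site, x$s))
  cat(sprintf("  FRic = %.4f  FEve = %s  FDis = %.4f  RaoQ = %.4f\n",
              x$fric, ifelse(is.na(x$feve), "NA", sprintf("%.4f", x$feve)),
              x$fdis, x$raoq))
  invisible(x)
}

#' Functional diversity indices for every site of a dataset
#'
#' @inheritParams fd_suite
#' @return data.frame with columns site, s, fric, feve, fdis, raoq.
#' @export
fd_table <- function(dataset, weighting = c("abundance", "biomass"),
                     hull_dim = 3L) {
  weighting <- match.arg(weighting)
  sites <- rownames(as_numeric_matrix(dataset$abundance_table))
  rows <- lapply(sites, function(s) {
    r <- fd_suite(dataset, s, weighting = weighting, hull_dim = hull_dim)
    data.frame(site = s, s = r$s, fric = r$fric, feve = r$feve,
               fdis = r$fdis, raoq = r$raoq, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
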