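# Brute-force reference implementations used to validate the fast paths.
# These deliberately take the slowest, most literal route (exhaustive
# spanning-tree enumeration via Pruefer sequences, double loops over species
# pairs) and share no code with the production functions they check.

#' Exhaustive minimum spanning tree (Cayley enumeration oracle)
#'
#' Enumerates all \eqn{S^{S-2}} labeled spanning trees through Pruefer
#' sequences and returns the minimum total length.  Only feasible for
#' small S (<= 7); intended for testing [minimum_spanning_tree()].
#'
#' @param dist symmetric distance matrix (S x S, 2 <= S <= 7).
#' @return list with `length` (minimal total weight) and `edges` (matrix of
#'   vertex pairs of one minimizing tree).
#' @export
oracle_mst <- function(dist) {
  D <- as_numeric_matrix(dist, "dist")
  S <- nrow(D)
  if (S < 2L || S > 7L)
    stop_fd("oracle_mst supports 2 <= S <= 7, got %d", S,
            class = "invalid_config")
  if (S == 2L)
    return(list(length = D[1L, 2L], edges = matrix(c(1L, 2L), 1L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), S - 2L)))
  best <- Inf; best_edges <- NULL
  for (r in seq_len(nrow(seqs))) {
    edges <- prufer_decode(seqs[r, ], S)
    w <- sum(D[edges])
    if (w < best) { best <- w; best_edges <- edges }
  }
  list(length = best, edges = best_edges)
}

prufer_decode <- function(code, n) {
  degree <- rep(1L, n)
  for (s in code) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (s in code) {
    leaf <- which.max(degree == 1L)  # smallest index with degree 1
    k <- k + 1L
    edges[k, ] <- c(min(leaf, s), max(leaf, s))
    degree[leaf] <- 0L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- c(min(last), max(last))
  edges
}

#' Double-loop Rao's quadratic entropy oracle
#' @param dist symmetric distance matrix.
#' @param p probability vector.
#' @export
oracle_rao <- function(dist, p) {
  D <- as_numeric_matrix(dist, "dist")
  S <- nrow(D)
  q <- 0
  for (i in seq_len(S - 1L))
    for (j in (i + 1L):S)
      q <- q + D[i, j] * p[i] * p[j]
  q
}

#' Elementwise functional dispersion oracle
#' @param points species coordinates.
#' @param a abundances.
#' @export
oracle_fdis <- function(points, a) {
  P <- as_numeric_matrix(points, "points")
  w <- a / sum(a)
  centroid <- rep(0, ncol(P))
  for (i in seq_len(nrow(P))) centroid <- centroid + w[i] * P[i, ]
  num <- 0
  for (i in seq_len(nrow(P)))
    num <- num + w[i] * sqrt(sum((P[i, ] - centroid)^2))
  num
}

#' Functional evenness oracle built on the exhaustive MST
#' @param dist symmetric distance matrix (S <= 7).
#' @param p relative abundances.
#' @export
oracle_feve <- function(dist, p) {
  D <- as_numeric_matrix(dist, "dist")
  S <- nrow(D)
  if (S < 3L) return(NA_real_)
  edges <- oracle_mst(D)$edges
  ew <- numeric(nrow(edges))
  for (l in seq_len(nrow(edges)))
    ew[l] <- D[edges[l, 1L], edges[l, 2L]] / (p[edges[l, 1L]] + p[edges[l, 2L]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}
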