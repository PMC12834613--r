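test_that("trait standardization z-scores over the pool and is idempotent", {
  X <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  Z <- standardize_traits(X)
  expect_equal(colMeans(Z), c(a = 0, b = 0))
  expect_equal(apply(Z, 2, sd), c(a = 1, b = 1))
  expect_equal(standardize_traits(Z), Z)

  Xc <- X; Xc[, 2] <- 5
  expect_error(standardize_traits(Xc), "b", class = "degenerate_trait")
})

test_that("Euclidean trait distances match hand geometry", {
  expect_equal(euclidean_distances(matrix(c(0, 3), 2, 1))[1, 2], 3)
  expect_equal(euclidean_distances(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  D <- euclidean_distances(rbind(c(1, 1), c(1, 1)))
  expect_equal(D[1, 2], 0)
})

test_that("convex hull volumes match elementary shapes and degeneracies", {
  expect_equal(convex_hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))), 1)
  expect_equal(convex_hull_volume(rbind(c(0, 0), c(2, 0), c(0, 2))), 2)
  expect_equal(convex_hull_volume(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_equal(convex_hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1))), 1)
  expect_equal(convex_hull_volume(c(2, 7, 4)), 5)     # 1-D range
  # interior points do not change the hull
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(convex_hull_volume(sq), 1)
  expect_error(convex_hull_volume(matrix(rnorm(20), 5, 4)),
               class = "unsupported_dimension")
})

test_that("MST matches exhaustive enumeration and vegan on small cases", {
  D <- euclidean_distances(matrix(c(0, 1, 3), 3, 1))
  mst <- minimum_spanning_tree(D)
  expect_equal(mst[, c("from", "to")],
               rbind(c(1, 2), c(2, 3)), ignore_attr = TRUE)
  expect_equal(sum(mst[, "weight"]), 3)

  # equilateral triangle: total length 2 x side whatever the tie-break
  Deq <- matrix(2, 3, 3); diag(Deq) <- 0
  expect_equal(sum(minimum_spanning_tree(Deq)[, "weight"]), 4)

  for (seed in 1:5) {
    com <- random_community(5, 2, seed)
    D5 <- euclidean_distances(com$traits)
    expect_equal(sum(minimum_spanning_tree(D5)[, "weight"]),
                 oracle_mst(D5)$length, tolerance = 1e-12)
  }
  skip_if_not_installed("vegan")
  com <- random_community(8, 3, 99)
  D8 <- euclidean_distances(com$traits)
  expect_equal(sum(minimum_spanning_tree(D8)[, "weight"]),
               sum(vegan::spantree(as.dist(D8))$dist), tolerance = 1e-12)
  expect_error(minimum_spanning_tree(matrix(0, 1, 1)), class = "undefined_mst")
})

test_that("FEve reproduces closed forms and stays in [0, 1]", {
  D <- euclidean_distances(matrix(c(0, 1, 2), 3, 1))
  expect_equal(functional_evenness(D, rep(1, 3) / 3), 1.0)
  D2 <- euclidean_distances(matrix(c(0, 1, 3), 3, 1))
  expect_equal(functional_evenness(D2, rep(1, 3) / 3), 2 / 3)
  expect_true(is.na(functional_evenness(matrix(c(0, 1, 1, 0), 2), c(.5, .5))))
  for (seed in 1:20) {
    com <- random_community(sample(3:8, 1), sample(1:3, 1), seed)
    f <- functional_evenness(euclidean_distances(com$traits), com$p)
    expect_gte(f, 0); expect_lte(f, 1)
  }
})

test_that("FDis matches hand-computed centroid distances", {
  expect_equal(functional_dispersion(matrix(c(0, 1, 2), 3, 1), rep(1, 3) / 3),
               2 / 3)
  expect_equal(functional_dispersion(matrix(c(0, 2, 4), 3, 1),
                                     c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(functional_dispersion(matrix(c(3, 7), 1, 2), 1), 0)
  expect_error(functional_dispersion(matrix(1:3, 3, 1), c(0, 0, 0)),
               class = "domain_error")
})

test_that("Rao's Q matches the pairwise sum and refuses unnormalized input", {
  D2 <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(rao_quadratic_entropy(D2, c(0.5, 0.5)), 0.5)
  D3 <- euclidean_distances(matrix(c(0, 1, 2), 3, 1))
  expect_equal(rao_quadratic_entropy(D3, rep(1, 3) / 3), 4 / 9)
  expect_equal(rao_quadratic_entropy(matrix(0, 1, 1), 1), 0)
  expect_error(rao_quadratic_entropy(D3, c(0.5, 0.4, 0.2)),
               class = "normalization_error")
})

test_that("Rao's equal-abundance identity links Q to the mean pairwise distance", {
  for (seed in 1:10) {
    S <- sample(3:7, 1)
    com <- random_community(S, 2, seed)
    D <- euclidean_distances(com$traits)
    q <- rao_quadratic_entropy(D, rep(1, S) / S)
    expect_equal(q, (S - 1) / (2 * S) * mean(D[upper.tri(D)]),
                 tolerance = 1e-12)
  }
})

test_that("FRic behaves as a hull-volume fraction", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(functional_richness(sq, 4), 0.25)   # inside a 2x2 reference
  pool <- rbind(sq * 2, c(1, 1))
  expect_equal(functional_richness(pool, pool), 1.0)
  expect_equal(functional_richness(matrix(c(1, 2), 1, 2), pool), 0)
  expect_error(functional_richness(sq, -1), class = "domain_error")
})

test_that("the fd_suite bundle obeys the degenerate and invariance contracts", {
  we <- worked_example()
  r2 <- fd_suite(we, "site2")   # sp5 has zero abundance at site2
  ds_drop <- we
  keep <- setdiff(colnames(we$abundance_table), "sp5")
  # removing the zero-abundance species must not change any index, as long
  # as the pool (trait standardization + reference hull) is preserved
  Z <- standardize_traits(we$trait_matrix)
  p <- we$abundance_table["site2", keep]
  pts <- Z[keep, ]
  D <- euclidean_distances(pts)
  expect_equal(r2$fric, functional_richness(pts, Z), tolerance = 1e-12)
  expect_equal(r2$feve, functional_evenness(D, p / sum(p)), tolerance = 1e-12)
  expect_equal(r2$fdis, functional_dispersion(pts, p), tolerance = 1e-12)
  expect_equal(r2$raoq, rao_quadratic_entropy(D, p / sum(p)),
               tolerance = 1e-12)

  # permuting species columns leaves all indices unchanged
  perm <- c(4, 2, 5, 1, 3)
  ds_perm <- we
  ds_perm$abundance_table <- we$abundance_table[, perm]
  ds_perm$trait_matrix <- we$trait_matrix[perm, ]
  for (s in rownames(we$abundance_table)) {
    a <- fd_suite(we, s); b <- fd_suite(ds_perm, s)
    expect_equal(a[c("fric", "feve", "fdis", "raoq")],
                 b[c("fric", "feve", "fdis", "raoq")], tolerance = 1e-12)
  }

  # single-species site: (0, missing, 0, 0)
  ds1 <- we
  ds1$abundance_table <- rbind(we$abundance_table,
                               solo = c(1, 0, 0, 0, 0))
  r <- fd_suite(ds1, "solo")
  expect_equal(r$fric, 0); expect_true(is.na(r$feve))
  expect_equal(r$fdis, 0); expect_equal(r$raoq, 0)
})

test_that("duplicating species with split abundance leaves RaoQ and FDis
           unchanged", {
  com <- random_community(5, 2, 7)
  D <- euclidean_distances(com$traits)
  fdis0 <- functional_dispersion(com$traits, com$p)
  rao0 <- rao_quadratic_entropy(D, com$p)
  dup <- rbind(com$traits, com$traits)
  pdup <- c(com$p, com$p) / 2
  Ddup <- euclidean_distances(dup)
  expect_equal(functional_dispersion(dup, pdup), fdis0, tolerance = 1e-12)
  expect_equal(rao_quadratic_entropy(Ddup, pdup), rao0, tolerance = 1e-12)
})

test_that("scaling standardized traits by c scales FDis and RaoQ by c and
           leaves FEve and FRic unchanged", {
  com <- random_community(6, 2, 13)
  c0 <- 2.5
  D <- euclidean_distances(com$traits)
  Dc <- euclidean_distances(c0 * com$traits)
  expect_equal(functional_dispersion(c0 * com$traits, com$p),
               c0 * functional_dispersion(com$traits, com$p))
  expect_equal(rao_quadratic_entropy(Dc, com$p),
               c0 * rao_quadratic_entropy(D, com$p))
  expect_equal(functional_evenness(Dc, com$p),
               functional_evenness(D, com$p))
  pool <- rbind(com$traits, random_community(4, 2, 14)$traits)
  expect_equal(functional_richness(c0 * com$traits, c0 * pool),
               functional_richness(com$traits, pool), tolerance = 1e-12)
})
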