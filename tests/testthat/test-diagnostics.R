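test_that("distance-preserving embeddings are the zero-distortion limit", {
  set.seed(41)
  pts <- matrix(rnorm(60), 30)
  d <- as.matrix(dist(pts))
  tc <- trustworthiness_continuity(d, pts, k = 10)
  expect_equal(tc$trustworthiness, 1)
  expect_equal(tc$continuity, 1)
  expect_equal(tc$product, 1)
  sc <- distance_correlations(d, pts)
  expect_equal(sc$pearson_r2, 1, tolerance = 1e-12)
  expect_equal(sc$kendall_tau, 1, tolerance = 1e-12)
  expect_equal(mst_extension_factor(d, pts), 1, tolerance = 1e-12)
  # scaling is free: mapped = 2 x original
  sc2 <- distance_correlations(d, pts * 2)
  expect_equal(sc2$pearson_r2, 1, tolerance = 1e-12)
  expect_equal(sc2$kendall_tau, 1, tolerance = 1e-12)
})

test_that("full-dimension PCoA of Euclidean-embeddable input has
           T = C = r2 = tau = 1 and MST extension 1", {
  set.seed(42)
  pts <- matrix(rnorm(75), 25)
  d <- as.matrix(dist(pts))
  pc <- pcoa(d, 24)
  q <- mapping_quality(d, pc, k = 10)
  expect_equal(q$trustworthiness, 1, tolerance = 1e-6)
  expect_equal(q$continuity, 1, tolerance = 1e-6)
  expect_equal(q$pearson_r2, 1, tolerance = 1e-6)
  expect_equal(q$kendall_tau, 1, tolerance = 1e-6)
  expect_equal(q$mst_extension, 1, tolerance = 1e-6)
})

test_that("trustworthiness/continuity equal the rank-list brute force and
           permutation degrades the product", {
  set.seed(43)
  td <- distance_matrix(random_trees(30, 10), "cid")
  d <- as.matrix(td)
  pts <- pcoa(td, 2)$points
  tc <- trustworthiness_continuity(d, pts, k = 10)
  ref <- oracle_trust_cont(d, pts, 10)
  expect_equal(tc$trustworthiness, unname(ref["trust"]), tolerance = 1e-12)
  expect_equal(tc$continuity, unname(ref["cont"]), tolerance = 1e-12)
  expect_error(trustworthiness_continuity(d, pts, k = 15), "n/2")

  set.seed(44)
  n <- 100
  pts2 <- matrix(rnorm(n * 2), n)
  d2 <- as.matrix(dist(pts2))
  perm <- sample(n)
  tcp <- trustworthiness_continuity(d2, pts2[perm, ], k = 10)
  expect_lt(tcp$product, 1)
})

test_that("Kendall tau matches a brute-force concordance count on
           scrambled distances", {
  set.seed(45)
  pts <- matrix(rnorm(40), 20)
  d <- as.matrix(dist(pts))
  # rank-scramble the mapped configuration
  pm <- pts[sample(20), ]
  sc <- distance_correlations(d, pm)
  x <- d[upper.tri(d)]
  dm <- as.matrix(dist(pm))
  y <- dm[upper.tri(dm)]
  expect_equal(sc$kendall_tau, oracle_kendall(x, y), tolerance = 1e-12)
  # constant mapped distances: degenerate flag
  const <- matrix(0, 20, 1)
  expect_true(distance_correlations(d, const)$degenerate)
})

test_that("MST is correct on hand examples and optimal against random
           spanning trees", {
  d3 <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3)
  expect_equal(mst_edges(d3), rbind(c(1L, 2L), c(2L, 3L)))
  # chain of equally spaced points maps to the chain itself
  dc <- as.matrix(dist(1:6))
  expect_equal(mst_edges(dc), cbind(1:5, 2:6))

  set.seed(46)
  pts <- matrix(rnorm(30), 15)
  d <- as.matrix(dist(pts))
  tot <- sum(d[mst_edges(d)])
  # igraph as independent oracle
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(tot, sum(igraph::E(igraph::mst(g))$weight),
               tolerance = 1e-12)
  # never longer than random spanning trees (random stars/chains)
  for (i in 1:100) {
    p <- sample(15)
    chain <- sum(d[cbind(p[-15], p[-1])])
    expect_lte(tot, chain + 1e-12)
  }
  dbad <- d; dbad[1, 2] <- dbad[2, 1] <- Inf
  expect_error(mst_edges(dbad), "finite")
})

test_that("MST extension factor: >= 1 always, and matches a first-principles
           recomputation when a coordinate is dropped", {
  set.seed(47)
  pts <- matrix(rnorm(40), 20)
  d <- as.matrix(dist(pts))
  emb <- pts[, 1, drop = FALSE]
  val <- mst_extension_factor(d, emb)
  expect_gte(val, 1)
  dm <- as.matrix(dist(emb))
  eo <- mst_edges(d); em <- mst_edges(dm)
  expect_equal(val, sum(dm[eo]) / sum(dm[em]), tolerance = 1e-12)
  set.seed(48)
  td <- distance_matrix(random_trees(25, 10), "cid")
  for (dd in 1:3)
    expect_gte(mst_extension_factor(td, pcoa(td, dd)), 1)
})

test_that("correlation dimension recovers the dimension of a line and a
           plane, and flags degenerate input", {
  d1 <- as.matrix(dist(line_points(500, seed = 49)))
  c1 <- correlation_dimension(d1)
  expect_equal(c1$dimension, 1, tolerance = 0.15)
  d2 <- as.matrix(dist(square_points(500, seed = 50)))
  c2 <- correlation_dimension(d2)
  expect_equal(c2$dimension, 2, tolerance = 0.125)  # 2 +- 0.25
  expect_length(c2$window, 2)
  z <- matrix(0, 10, 10)
  expect_true(correlation_dimension(z)$degenerate)
})

test_that("axis_covariate_r2: exact fit on axis 1, nulls near zero, and
           non-decreasing unadjusted R2", {
  set.seed(51)
  pts <- matrix(rnorm(500 * 6), 500)
  r <- axis_covariate_r2(pts, pts[, 1], max_d = 6)
  expect_equal(r[1], 1, tolerance = 1e-12)
  noise <- rnorm(500)
  rn <- axis_covariate_r2(pts, noise, max_d = 6)
  expect_true(all(abs(rn) < 0.05))
  # unadjusted R2 is non-decreasing in the axis prefix
  y <- rnorm(500)
  r2 <- vapply(1:6, function(k)
    summary(lm(y ~ pts[, 1:k, drop = FALSE]))$r.squared, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  expect_error(axis_covariate_r2(pts[1:5, ], noise[1:5], max_d = 6),
               "max_d|items")
})

test_that("truncating a pcoa embedding never increases the Shepard r2", {
  set.seed(52)
  td <- distance_matrix(random_trees(20, 12), "cid")
  r2s <- vapply(1:6, function(k)
    distance_correlations(td, pcoa(td, k))$pearson_r2, numeric(1))
  expect_true(all(diff(r2s) >= -1e-9))
})
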