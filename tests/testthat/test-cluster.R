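test_that("silhouette matches hand-computed configurations", {
  # two pairs of identical items in two clusters: perfect cohesion
  d <- matrix(10, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  expect_equal(silhouette_coefficient(d, c(1, 1, 2, 2)), 1)
  # all pairwise distances equal: any 2-partition scores 0
  e <- matrix(1, 6, 6); diag(e) <- 0
  expect_equal(silhouette_coefficient(e, rep(1:2, 3)), 0)
  # within 1, across 10: (10 - 1)/10
  f <- matrix(10, 4, 4); diag(f) <- 0
  f[1, 2] <- f[2, 1] <- 1
  f[3, 4] <- f[4, 3] <- 1
  expect_equal(silhouette_coefficient(f, c(1, 1, 2, 2)), 0.9)
  # singleton clusters score zero
  expect_equal(silhouette_coefficient(f, c(1, 2, 3, 3), per_item = TRUE)[1],
               0)
  expect_error(silhouette_coefficient(f, rep(1, 4)), "single cluster")
})

test_that("silhouette agrees with cluster::silhouette on random data", {
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnorm(40), 20)
    d <- as.matrix(dist(x))
    lab <- sample(1:3, 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    mine <- silhouette_coefficient(d, lab)
    ref <- mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("variation of information: identities, bounds and metric axioms", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2)), 2)
  expect_equal(variation_of_information(rep(1, 4), c(1, 1, 2, 2)), 1)
  expect_error(variation_of_information(1:3, 1:4), "same item")
  # symmetry + triangle inequality on random label triples
  set.seed(22)
  for (i in 1:200) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    c3 <- sample(1:4, 30, replace = TRUE)
    expect_equal(variation_of_information(a, b),
                 variation_of_information(b, a))
    expect_lte(variation_of_information(a, c3),
               variation_of_information(a, b) +
                 variation_of_information(b, c3) + 1e-9)
  }
})

test_that("VI of balanced 2-clusterings is bounded by 2 bits, attained by
           the crossing pair (exhaustive at n = 8)", {
  items <- 1:8
  halves <- combn(8, 4, simplify = FALSE)
  labs <- lapply(halves, function(h) as.integer(items %in% h) + 1L)
  vimax <- 0
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    v <- variation_of_information(labs[[i]], labs[[j]])
    expect_lte(v, 2 + 1e-12)
    vimax <- max(vimax, v)
  }
  expect_equal(vimax, 2)
})

test_that("all four methods recover well-separated clusters exactly", {
  set.seed(23)
  fx <- simulate_tree_clusters(25, 2, 10, n_moves = 1)
  td <- distance_matrix(fx$trees, "cid")
  for (m in cladospace:::.cluster_methods) {
    cl <- cluster_trees(td, m, 2, seed = 5)
    expect_equal(variation_of_information(cl, fx$labels), 0,
                 info = paste("method", m))
  }
  # reproducibility under a fixed seed
  c1 <- cluster_trees(td, "kmeans", 2, seed = 9)
  c2 <- cluster_trees(td, "kmeans", 2, seed = 9)
  expect_identical(c1$labels, c2$labels)
})

test_that("minimax linkage merges the closest pair first and boundary k
           works", {
  # 3 collinear points at distances (1, 1, 2): closest pair merges first
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  lab <- cladospace:::.minimax_cut(d, 2)
  expect_equal(lab[1] == lab[2] || lab[2] == lab[3], TRUE)
  expect_false(lab[1] == lab[3] && lab[1] != lab[2])
  set.seed(24)
  fx <- simulate_tree_clusters(10, 2, 4, n_moves = 1)
  td <- distance_matrix(fx$trees, "rf")
  cl <- cluster_trees(td, "hierarchical-minimax", 7, seed = 1)
  expect_equal(length(unique(cl$labels)), 7)
  expect_gte(min(table(cl$labels)), 1)
})

test_that("spectral clustering recovers tight blocks", {
  set.seed(25)
  d <- matrix(10 + runif(400, -0.1, 0.1), 20, 20)
  d[1:10, 1:10] <- matrix(runif(100, 0, 1e-3), 10)
  d[11:20, 11:20] <- matrix(runif(100, 0, 1e-3), 10)
  d <- (d + t(d)) / 2; diag(d) <- 0
  cl <- cluster_trees(d, "spectral", 2, seed = 1)
  expect_equal(variation_of_information(cl, rep(1:2, each = 10)), 0)
})

test_that("best_clustering selects k = 2 on the fixture, flags uniform
           trees as a single cluster, and breaks ties toward low k", {
  set.seed(26)
  fx <- simulate_tree_clusters(25, 2, 10, n_moves = 2)
  td <- distance_matrix(fx$trees, "cid")
  best <- best_clustering(td, k_range = 2:5, seed = 2)
  expect_equal(best$k, 2)
  expect_true(best$category %in% c("reasonable", "strong"))
  expect_gt(silhouette_coefficient(td, fx$labels), 0.5)

  # tie-break: zero matrix gives silhouette 0 everywhere -> k = 2, first
  # method wins
  z <- matrix(0, 6, 6)
  bz <- best_clustering(z, methods = c("pam", "kmeans"), k_range = 2:3,
                        seed = 1)
  expect_equal(bz$k, 2)
  expect_equal(bz$method, "pam")
  expect_true(bz$single_cluster)
})

test_that("uniform random trees lack clustering structure", {
  set.seed(27)
  trees <- random_trees(40, 20)
  td <- distance_matrix(trees, "cid")
  best <- best_clustering(td, methods = c("pam", "hierarchical-minimax"),
                          k_range = 2:5, seed = 3)
  expect_lt(best$silhouette, 0.5)
  expect_true(best$single_cluster)
})
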