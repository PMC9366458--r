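test_that("worked micro-examples give the hand-computed distances", {
  t5a <- nwk("((a,b),(c,d),e);")[[1]]
  t5b <- nwk("((a,c),(b,d),e);")[[1]]
  expect_equal(rf_distance(t5a, t5b), 4)
  expect_equal(quartet_distance(t5a, t5b), 5)
  expect_equal(vector_distance(tr_bal4(), tr_alt4(), "path"), 2)
  expect_equal(vector_distance(tr_bal4(), tr_alt4(), "sv"), 4)
  t3a <- nwk("((a,b),c);")[[1]]
  t3b <- nwk("((a,c),b);")[[1]]
  expect_equal(vector_distance(t3a, t3b, "kc"), sqrt(2))
})

test_that("identical trees are at distance zero under every metric", {
  set.seed(4)
  tr <- random_tree(9, rooted = TRUE)
  tru <- ape::unroot(tr)
  for (m in c("rf", "cid", "pid", "quartet", "path", "sv"))
    expect_equal(tree_distance(tru, tru, m), 0, tolerance = 1e-12)
  expect_equal(tree_distance(tr, tr, "kc"), 0)
})

test_that("distances validate their preconditions", {
  t1 <- tr_bal4()
  t2 <- nwk("((a,b),(c,e));")[[1]]
  expect_error(rf_distance(t1, t2), "leaf label set")
  expect_error(vector_distance(tr_star4(), tr_star4(), "kc"), "rooted")
  expect_error(info_distance(t1, t1, "matching-split"), "not implemented")
})

test_that("RF agrees with phangorn and respects the binary maximum", {
  set.seed(12)
  for (i in 1:40) {
    t1 <- random_tree(11); t2 <- random_tree(11)
    expect_equal(rf_distance(t1, t2), as.numeric(phangorn::RF.dist(t1, t2)))
    expect_lte(rf_distance(t1, t2), 16)  # 2(n-3)
  }
})

test_that("binary tree vs star tree yields the binary tree's information", {
  set.seed(5)
  for (n in c(6, 8)) {
    tr <- random_tree(n)
    star <- nwk(paste0("(", paste(sprintf("t%d", 1:n), collapse = ","),
                       ");"))[[1]]
    f <- cladospace:::.cid_features(cladospace:::.profile(tr))
    expect_equal(info_distance(tr, star, "clustering"), f$H)
    fp <- cladospace:::.pid_features(cladospace:::.profile(tr))
    expect_equal(info_distance(tr, star, "phylogenetic"), fp$H)
  }
})

test_that("quartet distance equals split-containment enumeration, and
           resolved-vs-unresolved counts", {
  expect_equal(quartet_distance(tr_star4(), tr_bal4()), 1)
  expect_equal(quartet_distance(tr_bal4(), tr_bal4(), normalized = TRUE), 0)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    t1 <- random_tree(n)
    t2 <- if (i %% 3 == 0) {
      # include multifurcating comparisons
      ape::di2multi(ape::compute.brlen(random_tree(n), 1), tol = 1)
    } else random_tree(n)
    if (length(t2$tip.label) != n) t2 <- random_tree(n)
    expect_equal(quartet_distance(t1, t2), oracle_quartet_distance(t1, t2))
  }
})

test_that("the exact assignment solver matches exhaustive matching", {
  set.seed(14)
  for (i in 1:20) {
    k1 <- sample(1:5, 1); k2 <- sample(1:5, 1)
    W <- matrix(runif(k1 * k2), k1, k2)
    expect_equal(cladospace:::.lap_max(W), oracle_best_matching(W),
                 tolerance = 1e-12)
  }
})

test_that("information distances equal exhaustive enumeration (n <= 8)", {
  set.seed(15)
  for (i in 1:30) {
    n <- sample(6:8, 1)
    t1 <- random_tree(n); t2 <- random_tree(n)
    expect_equal(info_distance(t1, t2, "clustering"), oracle_cid(t1, t2),
                 tolerance = 1e-9)
    expect_equal(info_distance(t1, t2, "phylogenetic"), oracle_pid(t1, t2),
                 tolerance = 1e-9)
  }
})

test_that("split information content matches exhaustive topology counts,
           including the a = 2 closed form", {
  for (n in 6:8) {
    set.seed(n)
    tr <- random_tree(n)
    pr <- cladospace:::.profile(tr)
    S <- cladospace:::.splits_logical(pr)
    f <- cladospace:::.pid_features(pr, S)
    labs <- pr$labels
    for (s in seq_len(nrow(S))) {
      side <- labs[S[s, ]]
      expect_equal(f$h[s], -log2(oracle_split_fraction(list(side), n)),
                   tolerance = 1e-9)
    }
    a <- rowSums(S)
    two <- which(pmin(a, n - a) == 2)
    ldf <- cladospace:::.ldf_odd
    for (s in two) {
      b <- max(a[s], n - a[s])
      expect_equal(f$h[s], ldf(2 * n - 5) - ldf(2 * b - 3),
                   tolerance = 1e-9)
    }
  }
})

test_that("metric axioms hold on sampled triples for every metric", {
  set.seed(16)
  n_triples <- 60
  mets <- c("rf", "cid", "pid", "quartet", "path", "kc", "sv")
  for (i in seq_len(n_triples)) {
    rooted <- random_trees(3, 8, rooted = TRUE)
    unrooted <- lapply(rooted, ape::unroot)
    for (m in mets) {
      trs <- if (m == "kc") rooted else unrooted
      dxy <- tree_distance(trs[[1]], trs[[2]], m)
      dyx <- tree_distance(trs[[2]], trs[[1]], m)
      dxz <- tree_distance(trs[[1]], trs[[3]], m)
      dyz <- tree_distance(trs[[2]], trs[[3]], m)
      expect_equal(dxy, dyx, tolerance = 1e-12)
      expect_equal(tree_distance(trs[[1]], trs[[1]], m), 0,
                   tolerance = 1e-12)
      expect_lte(dxz, dxy + dyz + 1e-9)
    }
  }
})

test_that("distance_matrix is symmetric, zero-diagonal and supports
           deduplication with recoverable multiplicities", {
  set.seed(17)
  trees <- random_trees(12, 8)
  for (m in c("rf", "cid", "path", "sv")) {
    td <- distance_matrix(trees, m)
    d <- as.matrix(td)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
  }
  # three identical trees -> zero matrix
  same <- nwk("((a,b),(c,d));\n((a,b),(c,d));\n((a,b),(c,d));")
  expect_true(all(as.matrix(distance_matrix(same, "rf")) == 0))
  # 10 copies of 2 topologies -> 2 x 2 after dedup, expansion recoverable
  ten <- c(rep(nwk("((a,b),(c,d),e);"), 5), rep(nwk("((a,c),(b,d),e);"), 5))
  class(ten) <- "multiPhylo"
  td <- distance_matrix(ten, "rf", dedup = TRUE)
  expect_equal(dim(as.matrix(td)), c(2L, 2L))
  expect_equal(sort(td$multiplicity), c(5L, 5L))
  expect_length(td$map, 10)
  full <- as.matrix(td)[td$map, td$map]
  expect_equal(dim(full), c(10L, 10L))
  expect_equal(full[1, 6], 4)
  expect_error(distance_matrix(nwk("((a,b),c);\n((a,d),c);"), "rf"),
               "differing leaf sets")
})

test_that("saturation contrast: uniform 11-leaf pairs usually saturate RF
           but essentially never the clustering information distance", {
  set.seed(18)
  rf_sat <- 0; cid_sat <- 0; np <- 300
  for (i in seq_len(np)) {
    t1 <- random_tree(11); t2 <- random_tree(11)
    if (rf_distance(t1, t2) == 16) rf_sat <- rf_sat + 1
    f1 <- cladospace:::.cid_features(cladospace:::.profile(t1))
    f2 <- cladospace:::.cid_features(cladospace:::.profile(t2))
    if (cladospace:::.d_info(f1, f2, "cid") >= (f1$H + f2$H) * (1 - 1e-9))
      cid_sat <- cid_sat + 1
  }
  expect_gt(rf_sat / np, 0.5)   # large majority saturate
  expect_equal(cid_sat, 0)      # CID essentially never attains its maximum
})
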