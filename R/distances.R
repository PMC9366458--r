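# Pairwise cladogram distances.
#
# Eight metrics: rf, cid (clustering information), pid (phylogenetic
# information), ms (matching split information; declared but not scored
# here), quartet, path, kc (Kendall-Colijn at lambda = 0) and sv (split size
# vector).  Information distances are reported in total bits (per-split
# entropies scaled by n); RF and quartet distances are exact integers.

.metric_names <- c("rf", "cid", "pid", "ms", "quartet", "path", "kc", "sv")

.canon_metric <- function(metric) {
  m <- tolower(metric)
  m <- switch(m,
    "rf" = , "robinson-foulds" = "rf",
    "cid" = , "ci" = , "clustering" = "cid",
    "pid" = , "pi" = , "phylogenetic" = "pid",
    "ms" = , "msid" = , "matching-split" = "ms",
    "quartet" = , "qd" = , "q" = "quartet",
    "path" = , "pt" = "path",
    "kc" = , "kendall-colijn" = "kc",
    "sv" = , "split-size" = "sv",
    stop("unknown metric: ", metric))
  m
}

# log2 of the double factorial of an odd integer >= -1 ((-1)!! = 1).
.ldf_odd <- function(x) {
  k <- (x + 1) / 2
  (lgamma(2 * k + 1) - k * log(2) - lgamma(k + 1)) / log(2)
}

# --- per-tree features -----------------------------------------------------

# Clustering-information features of a split set.
.cid_features <- function(pr, S = NULL) {
  if (is.null(S)) S <- .splits_logical(pr)
  n <- pr$n
  a <- rowSums(S)
  p <- a / n
  hr <- -(.xlog2(p) + .xlog2(1 - p))  # per-leaf entropy of each split
  list(S = S, a = a, hr = hr, h = n * hr, H = n * sum(hr), n = n)
}

# Phylogenetic-information features.
.pid_features <- function(pr, S = NULL) {
  if (is.null(S)) S <- .splits_logical(pr)
  n <- pr$n
  a <- rowSums(S)
  h <- .ldf_odd(2 * n - 5) - .ldf_odd(2 * a - 3) - .ldf_odd(2 * (n - a) - 3)
  list(S = S, a = a, h = h, H = sum(h), n = n)
}

# Quartet status per 4-leaf subset: 0 unresolved, 1/2/3 the resolution,
# determined from unit-length path distances by the four-point condition.
.quartet_combs <- function(n) utils::combn(n, 4L)

.quartet_status <- function(P, combs) {
  a <- combs[1L, ]; b <- combs[2L, ]; c <- combs[3L, ]; d <- combs[4L, ]
  s1 <- P[cbind(a, b)] + P[cbind(c, d)]
  s2 <- P[cbind(a, c)] + P[cbind(b, d)]
  s3 <- P[cbind(a, d)] + P[cbind(b, c)]
  st <- integer(length(s1))
  st[s1 < s2 & s1 < s3] <- 1L
  st[s2 < s1 & s2 < s3] <- 2L
  st[s3 < s1 & s3 < s2] <- 3L
  st
}

# --- pairwise cores --------------------------------------------------------

.d_rf <- function(k1, k2) {
  length(k1) + length(k2) - 2L * length(intersect(k1, k2))
}

# Shared clustering information (total bits) for every split pair.
.cid_shared <- function(f1, f2) {
  n <- f1$n
  k1 <- length(f1$a); k2 <- length(f2$a)
  if (k1 == 0L || k2 == 0L) return(matrix(0, k1, k2))
  N11 <- f1$S %*% t(f2$S)
  A1 <- matrix(f1$a, k1, k2)
  A2 <- matrix(f2$a, k1, k2, byrow = TRUE)
  N10 <- A1 - N11
  N01 <- A2 - N11
  N00 <- n - A1 - A2 + N11
  negHj <- .xlog2(N11 / n) + .xlog2(N10 / n) + .xlog2(N01 / n) +
    .xlog2(N00 / n)
  shared <- n * (outer(f1$hr, f2$hr, "+") + negHj)
  pmax(shared, 0)
}

# Shared phylogenetic information for every split pair (0 if incompatible).
.pid_shared <- function(f1, f2) {
  n <- f1$n
  k1 <- length(f1$a); k2 <- length(f2$a)
  if (k1 == 0L || k2 == 0L) return(matrix(0, k1, k2))
  N11 <- f1$S %*% t(f2$S)
  A1 <- matrix(f1$a, k1, k2)
  A2 <- matrix(f2$a, k1, k2, byrow = TRUE)
  N10 <- A1 - N11
  N01 <- A2 - N11
  N00 <- n - A1 - A2 + N11
  compat <- N11 == 0 | N10 == 0 | N01 == 0 | N00 == 0
  # orient each compatible pair as inner set within an outer side:
  # inner | (outer \ inner) = c leaves | complement of outer = b leaves
  inner <- ifelse(N01 == 0, A2, ifelse(N10 == 0, A1,
           ifelse(N11 == 0, A2, n - A2)))
  bmat <- ifelse(N01 == 0, n - A1, ifelse(N10 == 0, n - A2,
          ifelse(N11 == 0, A1, n - A1)))
  cmat <- ifelse(N01 == 0, A1 - A2, ifelse(N10 == 0, A2 - A1,
          ifelse(N11 == 0, n - A1 - A2, A1 - (n - A2))))
  hboth <- .ldf_odd(2 * n - 5) -
    (.ldf_odd(2 * inner - 3) + .ldf_odd(2 * bmat - 3) +
       .ldf_odd(2 * cmat - 1))
  shared <- outer(f1$h, f2$h, "+") - hboth
  shared[!compat] <- 0
  pmax(shared, 0)
}

# Maximum-weight one-to-one matching score (rectangular, zero-padded).
.lap_max <- function(w) {
  k1 <- nrow(w); k2 <- ncol(w)
  if (k1 == 0L || k2 == 0L) return(0)
  m <- max(k1, k2)
  cost <- matrix(0, m, m)
  cost[seq_len(k1), seq_len(k2)] <- -w
  -.solve_assignment_cpp(cost)$cost
}

.d_info <- function(f1, f2, kind) {
  shared <- if (kind == "cid") .cid_shared(f1, f2) else .pid_shared(f1, f2)
  max(0, f1$H + f2$H - 2 * .lap_max(shared))  # clamp fp residue
}

# --- public pairwise distances --------------------------------------------

#' Robinson-Foulds distance
#'
#' Counts the nontrivial splits present in exactly one of the two trees.
#' For two binary n-leaf trees the maximum is 2(n-3).
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @return a nonnegative integer.
#' @examples
#' tr <- read_trees(text = "((a,b),(c,d),e);\n((a,c),(b,d),e);")
#' rf_distance(tr[[1]], tr[[2]])
#' @export
rf_distance <- function(t1, t2) {
  pr1 <- .profile(t1); pr2 <- .profile(t2)
  .check_same_leaves(pr1, pr2)
  .d_rf(.split_keys(.splits_logical(pr1)), .split_keys(.splits_logical(pr2)))
}

#' Information-theoretic tree distance
#'
#' Generalized Robinson-Foulds distances: splits of the two trees are paired
#' one-to-one so as to maximise the information they hold in common (an
#' exact linear assignment); the distance is the information not held in
#' common, \eqn{H(T1) + H(T2) - 2 M^*}, in total bits.
#'
#' For \code{kind = "clustering"}, the information content of a split with
#' sides of a and b leaves is n times the entropy of the leaf-membership
#' indicator, and shared information is n times the mutual information of
#' the 2x2 joint membership counts.  For \code{kind = "phylogenetic"},
#' information content is the log-probability that a uniformly chosen binary
#' topology contains the split, and a compatible split pair shares
#' \eqn{h(S1) + h(S2) - h(S1 \wedge S2)} bits, where the joint content is
#' computed from an exact count of topologies containing both splits;
#' incompatible pairs share nothing.  Unmatched splits contribute their full
#' information to the distance.
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set (n >= 4).
#' @param kind \code{"clustering"}, \code{"phylogenetic"} or
#'   \code{"matching-split"} (the last is declared but its pair scoring is
#'   not implemented here).
#' @return nonnegative distance in bits; 0 for identical topologies.
#' @examples
#' tr <- read_trees(text = "((a,b),(c,d),e);\n((a,c),(b,d),e);")
#' info_distance(tr[[1]], tr[[2]], "clustering")
#' @export
info_distance <- function(t1, t2,
                          kind = c("clustering", "phylogenetic",
                                   "matching-split")) {
  kind <- match.arg(kind)
  if (kind == "matching-split")
    stop("matching-split information scoring is not implemented")
  kind <- if (kind == "clustering") "cid" else "pid"
  pr1 <- .profile(t1); pr2 <- .profile(t2)
  .check_same_leaves(pr1, pr2)
  if (pr1$n < 4L) stop("information distances require n >= 4 leaves")
  f <- if (kind == "cid") .cid_features else .pid_features
  .d_info(f(pr1), f(pr2), kind)
}

#' Quartet distance
#'
#' Counts the 4-leaf subsets whose induced quartet status (one of the three
#' resolutions, or unresolved) differs between the two trees; ranges from 0
#' to choose(n, 4).
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set (n >= 4).
#' @param normalized divide by choose(n, 4)?
#' @return count (or fraction) of differing quartets.
#' @examples
#' tr <- read_trees(text = "((a,b),(c,d),e);\n((a,c),(b,d),e);")
#' quartet_distance(tr[[1]], tr[[2]])
#' @export
quartet_distance <- function(t1, t2, normalized = FALSE) {
  pr1 <- .profile(t1); pr2 <- .profile(t2)
  .check_same_leaves(pr1, pr2)
  if (pr1$n < 4L) stop("the quartet distance requires n >= 4 leaves")
  combs <- .quartet_combs(pr1$n)
  d <- sum(.quartet_status(.path_matrix(pr1), combs) !=
             .quartet_status(.path_matrix(pr2), combs))
  if (normalized) d / ncol(combs) else d
}

#' Euclidean vector-based tree distance
#'
#' The Euclidean norm of the difference between the trees' pair vectors:
#' \code{"path"} (leaf-to-leaf edge counts), \code{"kc"} (Kendall-Colijn at
#' lambda = 0, i.e. root-to-MRCA depths; rooted trees only) or \code{"sv"}
#' (split size vector).
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @param kind \code{"path"}, \code{"kc"} or \code{"sv"}.
#' @return nonnegative real distance.
#' @examples
#' tr <- read_trees(text = "((a,b),(c,d));\n((a,c),(b,d));")
#' vector_distance(tr[[1]], tr[[2]], "path")
#' vector_distance(tr[[1]], tr[[2]], "sv")
#' @export
vector_distance <- function(t1, t2, kind = c("path", "kc", "sv")) {
  kind <- match.arg(kind)
  pr1 <- .profile(t1); pr2 <- .profile(t2)
  .check_same_leaves(pr1, pr2)
  m1 <- switch(kind,
    path = .path_matrix(pr1),
    sv = .sv_matrix(pr1),
    kc = {
      if (!pr1$rooted || !pr2$rooted)
        stop("the KC distance requires rooted trees")
      .mrca_depth(pr1)
    })
  m2 <- switch(kind,
    path = .path_matrix(pr2),
    sv = .sv_matrix(pr2),
    kc = .mrca_depth(pr2))
  sqrt(sum((.ut(m1) - .ut(m2))^2))
}

#' Pairwise tree distance under a named metric
#'
#' Dispatches to the individual distance functions.  Metric names (with
#' synonyms): \code{"rf"}, \code{"cid"} (clustering information),
#' \code{"pid"} (phylogenetic information), \code{"ms"}, \code{"quartet"},
#' \code{"path"}, \code{"kc"}, \code{"sv"}.
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @param metric metric name.
#' @return the distance.
#' @export
tree_distance <- function(t1, t2, metric = "cid") {
  m <- .canon_metric(metric)
  switch(m,
    rf = rf_distance(t1, t2),
    cid = info_distance(t1, t2, "clustering"),
    pid = info_distance(t1, t2, "phylogenetic"),
    ms = info_distance(t1, t2, "matching-split"),
    quartet = quartet_distance(t1, t2),
    path = vector_distance(t1, t2, "path"),
    kc = vector_distance(t1, t2, "kc"),
    sv = vector_distance(t1, t2, "sv"))
}
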