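# Uniformly distributed random tree topologies and clustered fixtures.

# Rooted binary topology drawn uniformly from the (2n-3)!! labelled rooted
# topologies, by sequential insertion: leaf k is attached to an edge chosen
# uniformly among the 2k-3 edges of the current tree (counting the stem edge
# above the root), which is realised by picking any current node uniformly
# and interposing a new internal node above it.
# Returns parent pointers: leaves 1..n, internals n+1..2n-1.
.rtopo_parent <- function(n) {
  nn <- 2L * n - 1L
  parent <- integer(nn)
  parent[1L] <- parent[2L] <- n + 1L
  root <- n + 1L
  if (n >= 3L) {
    u01 <- runif(n - 2L)
    nextint <- n + 1L
    for (k in 3L:n) {
      m <- 2L * k - 3L  # nodes currently present
      idx <- 1L + as.integer(floor(u01[k - 2L] * m))
      if (idx > m) idx <- m
      u <- if (idx < k) idx else n + idx - (k - 1L)
      nextint <- nextint + 1L
      pu <- parent[u]
      parent[u] <- nextint
      parent[k] <- nextint
      parent[nextint] <- pu
      if (pu == 0L) root <- nextint
    }
  }
  list(parent = parent, root = root, n = n)
}

# Unrooted binary topology uniform over (2n-5)!! labelled topologies, via the
# bijection with rooted topologies on n-1 leaves: generate a rooted tree on
# leaves {2..n}, then attach leaf 1 to its root (which becomes the basal
# trichotomy of the unrooted representation).
# Leaves 1..n, internals n+1..2n-2.
.utopo_parent <- function(n) {
  if (n == 3L) {
    parent <- c(4L, 4L, 4L, 0L)
    return(list(parent = parent, root = 4L, n = n))
  }
  rt <- .rtopo_parent(n - 1L)
  k <- n - 1L
  # remap: rooted leaf j -> leaf j+1; rooted internal k+i -> n+i
  nn <- 2L * n - 2L
  parent <- integer(nn)
  map <- c(seq_len(k) + 1L, n + seq_len(k - 1L))
  for (v in seq_along(rt$parent)) {
    p <- rt$parent[v]
    parent[map[v]] <- if (p == 0L) 0L else map[p]
  }
  root <- map[rt$root]
  parent[1L] <- root
  list(parent = parent, root = root, n = n)
}

.parent_to_phylo <- function(pt, labels = NULL) {
  n <- pt$n
  parent <- pt$parent
  nn <- length(parent)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  # renumber internals so the root is n+1 and internals follow in preorder
  newid <- integer(nn)
  newid[seq_len(n)] <- seq_len(n)
  ord <- pt$root
  cur <- pt$root
  while (length(cur)) {
    kids <- which(parent %in% cur)
    kids <- kids[kids > n]
    ord <- c(ord, kids)
    cur <- kids
  }
  newid[ord] <- n + seq_along(ord)
  child <- which(parent > 0L)
  edge <- cbind(newid[parent[child]], newid[child])
  edge <- edge[order(edge[, 1L], edge[, 2L]), , drop = FALSE]
  phy <- list(edge = edge, tip.label = labels, Nnode = nn - n)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Draw a random binary tree topology from the uniform distribution
#'
#' Samples uniformly from all labelled binary topologies ((2n-5)!! unrooted,
#' (2n-3)!! rooted) by sequential insertion of each leaf onto a uniformly
#' chosen edge.  Reproducible under \code{set.seed}.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param rooted logical; draw a rooted topology?
#' @param labels optional leaf labels (default \code{t1..tn}).
#' @return a \code{phylo} tree without branch lengths.
#' @examples
#' set.seed(1)
#' random_tree(8)
#' @export
random_tree <- function(n_leaves, rooted = FALSE, labels = NULL) {
  if (n_leaves < 3L) stop("n_leaves must be >= 3")
  pt <- if (rooted) .rtopo_parent(as.integer(n_leaves))
        else .utopo_parent(as.integer(n_leaves))
  .parent_to_phylo(pt, labels)
}

#' Draw several random tree topologies
#'
#' @param n number of trees.
#' @inheritParams random_tree
#' @return a \code{multiPhylo} list.
#' @export
random_trees <- function(n, n_leaves, rooted = FALSE, labels = NULL) {
  out <- replicate(n, random_tree(n_leaves, rooted, labels),
                   simplify = FALSE)
  class(out) <- "multiPhylo"
  out
}

#' Simulate clustered sets of trees
#'
#' Draws \code{n_clusters} independent uniform reference topologies, then
#' derives \code{trees_per_cluster} members per cluster by applying
#' \code{n_moves} random nearest-neighbour-interchange (NNI) moves to the
#' reference.  Small move counts give tight clusters.
#'
#' @param n_leaves leaves per tree.
#' @param n_clusters number of clusters (>= 1).
#' @param trees_per_cluster members per cluster.
#' @param n_moves NNI perturbation count per member.
#' @param rooted logical; generate rooted trees?
#' @return list with components \code{trees} (\code{multiPhylo}) and
#'   \code{labels} (integer cluster id per tree, aligned with tree order).
#' @examples
#' set.seed(1)
#' fx <- simulate_tree_clusters(10, 2, 5, n_moves = 1)
#' table(fx$labels)
#' @export
simulate_tree_clusters <- function(n_leaves, n_clusters, trees_per_cluster,
                                   n_moves = 1L, rooted = FALSE) {
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  trees <- list()
  labels <- integer(0L)
  for (cl in seq_len(n_clusters)) {
    ref <- random_tree(n_leaves, rooted = rooted)
    for (j in seq_len(trees_per_cluster)) {
      tr <- ref
      if (n_moves > 0L) for (m in seq_len(n_moves)) tr <- .random_nni(tr)
      trees[[length(trees) + 1L]] <- tr
      labels <- c(labels, cl)
    }
  }
  class(trees) <- "multiPhylo"
  list(trees = trees, labels = labels)
}

# Apply one NNI move across a uniformly chosen internal edge.
.random_nni <- function(phy) {
  n <- length(phy$tip.label)
  edge <- phy$edge
  # internal edges: both endpoints internal nodes
  int <- which(edge[, 2L] > n)
  if (!length(int)) return(phy)
  e <- int[sample.int(length(int), 1L)]
  a <- edge[e, 1L]; b <- edge[e, 2L]
  # children of b, and other children of a
  bkids <- edge[edge[, 1L] == b, 2L]
  akids <- setdiff(edge[edge[, 1L] == a, 2L], b)
  if (!length(akids) || length(bkids) < 2L) return(phy)
  x <- akids[sample.int(length(akids), 1L)]
  y <- bkids[sample.int(length(bkids), 1L)]
  # swap subtrees x and y
  ix <- which(edge[, 1L] == a & edge[, 2L] == x)
  iy <- which(edge[, 1L] == b & edge[, 2L] == y)
  edge[ix, 2L] <- y
  edge[iy, 2L] <- x
  phy$edge <- edge
  ape::reorder.phylo(phy, "cladewise")
}
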