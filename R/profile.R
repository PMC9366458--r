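# Internal tree decomposition ("profile") shared by all distance code.
#
# A profile stores, for one tree, the parent pointers, node depths and the
# leaf-membership matrix of every node, with leaves indexed in a canonical
# order (alphabetical by label) so that vectors and splits from two trees on
# the same leaf set are directly comparable.

# Build a profile from parent pointers.
# parent: integer vector over node ids 1..nn (leaves 1..n first), 0 at root.
# rank:   canonical column for each leaf (rank[i] = position of leaf i's label
#         in the sorted label vector).
.profile_core <- function(parent, root, n, rank, labels) {
  nn <- length(parent)
  depth <- integer(nn)
  ord <- integer(nn)
  ord[1L] <- root
  pos <- 1L
  cur <- root
  while (length(cur)) {
    kids <- which(parent %in% cur)
    if (!length(kids)) break
    depth[kids] <- depth[parent[kids]] + 1L
    ord[pos + seq_along(kids)] <- kids
    pos <- pos + length(kids)
    cur <- kids
  }
  M <- matrix(FALSE, nn, n)
  M[cbind(seq_len(n), rank)] <- TRUE
  for (v in rev(ord)) {
    if (v == root) next
    p <- parent[v]
    M[p, ] <- M[p, ] | M[v, ]
  }
  nchild <- tabulate(parent[parent > 0L], nn)
  internal <- which(nchild > 0L)
  nonroot_int <- internal[internal != root]
  list(n = n, nn = nn, parent = parent, root = root, depth = depth,
       M = M, rank = rank, labels = labels, internal = internal,
       nchild = nchild, root_degree = nchild[root],
       rooted = nchild[root] == 2L,
       binary = all(nchild[nonroot_int] == 2L) && nchild[root] %in% c(2L, 3L))
}

# Profile from an ape phylo object.
.profile <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree")
  n <- length(phy$tip.label)
  if (n < 3L) stop("trees must have at least 3 leaves")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1L])
  nn <- n + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- which(parent == 0L & seq_len(nn) > n)
  if (length(root) != 1L) stop("tree is not connected or has no root node")
  rank <- match(phy$tip.label, sort(phy$tip.label))
  .profile_core(parent, root, n, rank, sort(phy$tip.label))
}

# Depth (edge count from root) of the MRCA of each canonical leaf pair,
# as a symmetric n x n matrix (diagonal meaningless).
.mrca_depth <- function(pr) {
  D <- matrix(0, pr$n, pr$n)
  ints <- pr$internal[pr$internal != pr$root]
  ints <- ints[order(pr$depth[ints])]
  for (v in ints) {
    idx <- which(pr$M[v, ])
    D[idx, idx] <- pr$depth[v]
  }
  D
}

# Leaf depths in canonical order.
.leaf_depth <- function(pr) {
  ld <- integer(pr$n)
  ld[pr$rank] <- pr$depth[seq_len(pr$n)]
  ld
}

# Path-length (edge count) matrix between leaves of the *unrooted* topology.
.path_matrix <- function(pr, D = NULL) {
  if (is.null(D)) D <- .mrca_depth(pr)
  ld <- .leaf_depth(pr)
  P <- outer(ld, ld, "+") - 2 * D
  if (pr$root_degree == 2L) P <- P - (D == 0)  # degree-2 root is suppressed
  diag(P) <- 0
  P
}

# Nontrivial splits of the unrooted topology: logical matrix, one canonical
# side per row (the side *not* containing the first canonical leaf).
.splits_logical <- function(pr) {
  cand <- pr$internal[pr$internal != pr$root]
  if (!length(cand)) return(matrix(FALSE, 0L, pr$n))
  S <- pr$M[cand, , drop = FALSE]
  flip <- S[, 1L]
  S[flip, ] <- !S[flip, , drop = FALSE]
  sz <- rowSums(S)
  S <- S[sz >= 2L & sz <= pr$n - 2L, , drop = FALSE]
  if (nrow(S) > 1L) S <- S[!duplicated(.split_keys(S)), , drop = FALSE]
  S
}

# Compact, exact hash of split rows (doubles are exact up to 2^53, so bit
# masks are safe for n <= 52; larger trees fall back to string keys).
.split_keys <- function(S) {
  n <- ncol(S)
  if (n == 0L || nrow(S) == 0L) {
    return(if (n <= 52L) numeric(0L) else character(0L))
  }
  if (n <= 52L) as.vector(S %*% 2^(seq_len(n) - 1L))
  else apply(S, 1L, function(r) paste(which(r), collapse = ","))
}

# Split-size matrix: entry (i, j) is the size of the smallest nontrivial
# split side containing both canonical leaves i and j, or n if none does.
.sv_matrix <- function(pr, S = NULL) {
  if (is.null(S)) S <- .splits_logical(pr)
  n <- pr$n
  E <- matrix(n, n, n)
  if (nrow(S)) {
    sz <- rowSums(S)
    sides <- rbind(S, !S)
    sizes <- c(sz, n - sz)
    for (i in order(sizes, decreasing = TRUE)) {
      idx <- which(sides[i, ])
      E[idx, idx] <- sizes[i]
    }
  }
  diag(E) <- 0
  E
}

# Values of a symmetric pair matrix in canonical pair order (lexicographic
# by canonical leaf index), with "label|label" names.
.pair_vector <- function(m, labels) {
  n <- nrow(m)
  pr <- utils::combn(n, 2L)
  v <- m[cbind(pr[1L, ], pr[2L, ])]
  names(v) <- paste(labels[pr[1L, ]], labels[pr[2L, ]], sep = "|")
  v
}

# Upper-triangle values in a fixed (column-major) order; used internally
# where names are not needed.  Consistent across trees on one leaf set.
.ut <- function(m) m[upper.tri(m)]

.xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  dim(out) <- dim(p)
  out
}

.check_same_leaves <- function(pr1, pr2) {
  if (pr1$n != pr2$n || !identical(pr1$labels, pr2$labels))
    stop("trees must share an identical leaf label set")
}
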