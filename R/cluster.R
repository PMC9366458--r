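# Cluster detection over tree distance matrices, silhouette-based model
# selection, and clustering comparison by variation of information.

.cluster_methods <- c("kmeans", "pam", "hierarchical-minimax", "spectral")

#' Cluster trees from a distance matrix
#'
#' Four clustering approaches over a precomputed tree distance matrix:
#' \itemize{
#'   \item \code{"kmeans"}: Hartigan-Wong K-means with 3 random starts and at
#'     most 42 iterations, applied to the rows of the distance matrix as
#'     feature vectors;
#'   \item \code{"pam"}: partitioning around medoids on the distances
#'     directly, with random starts where the installed \code{cluster}
#'     package supports them;
#'   \item \code{"hierarchical-minimax"}: agglomerative clustering under
#'     minimax linkage (each merge minimises the radius of the smallest
#'     ball, centred on a member prototype, covering the merged cluster),
#'     cut at k;
#'   \item \code{"spectral"}: a Gaussian affinity (bandwidth = median
#'     off-diagonal distance) is built from the distances, items are
#'     embedded in the leading eigenvectors of the normalized graph
#'     Laplacian, and PAM is applied in that eigenspace.
#' }
#'
#' @param distmat a \code{tree_dist}, \code{dist} or symmetric matrix.
#' @param method one of \code{"kmeans"}, \code{"pam"},
#'   \code{"hierarchical-minimax"}, \code{"spectral"}.
#' @param k number of clusters, 2 <= k < n.
#' @param seed integer seed for the stochastic methods.
#' @return an object of class \code{tree_clustering}: list with
#'   \code{labels}, \code{method}, \code{k}, \code{silhouette},
#'   \code{category} and \code{seed}.
#' @examples
#' set.seed(1)
#' fx <- simulate_tree_clusters(12, 2, 6, n_moves = 1)
#' td <- distance_matrix(fx$trees, "cid")
#' cluster_trees(td, "pam", 2)
#' @export
cluster_trees <- function(distmat, method = .cluster_methods, k,
                          seed = 1L) {
  method <- match.arg(method)
  d <- .as_dmat(distmat)
  n <- nrow(d)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n")
  if (!is.null(seed)) set.seed(seed)
  labels <- switch(method,
    "kmeans" = .kmeans_labels(d, k),
    "pam" = .pam_labels(stats::as.dist(d), k, diss = TRUE),
    "hierarchical-minimax" = .minimax_cut(d, k),
    "spectral" = .pam_labels(.spectral_embed(d, k), k, diss = FALSE))
  sil <- silhouette_coefficient(d, labels)
  structure(list(labels = labels, method = method, k = k,
                 silhouette = sil, category = .structure_category(sil),
                 seed = seed),
            class = "tree_clustering")
}

.structure_category <- function(sil) {
  if (sil > 0.7) "strong"
  else if (sil > 0.5) "reasonable"
  else if (sil > 0.25) "weak"
  else "none"
}

.kmeans_labels <- function(d, k) {
  res <- tryCatch(
    stats::kmeans(d, centers = k, nstart = 3L, iter.max = 42L),
    error = function(e) NULL)
  if (!is.null(res)) return(unname(res$cluster))
  # degenerate input (e.g. fewer distinct rows than k): seed distinct rows
  ur <- unique(as.data.frame(d))
  if (nrow(ur) >= k) {
    res <- stats::kmeans(d, centers = as.matrix(ur[seq_len(k), ]),
                         iter.max = 42L)
    return(unname(res$cluster))
  }
  lab <- match(apply(d, 1L, paste, collapse = ","),
               unique(apply(d, 1L, paste, collapse = ",")))
  .force_k(lab, k)
}

# Ensure exactly k nonempty clusters by splitting the largest clusters.
.force_k <- function(lab, k) {
  while (length(unique(lab)) < k) {
    tab <- table(lab)
    big <- as.integer(names(tab)[which.max(tab)])
    idx <- which(lab == big)
    lab[idx[1L]] <- max(lab) + 1L
  }
  match(lab, unique(lab))
}

.pam_labels <- function(x, k, diss) {
  f <- names(formals(cluster::pam))
  res <- if (all(c("variant", "nstart", "medoids") %in% f)) {
    cluster::pam(x, k, diss = diss, variant = "faster",
                 medoids = "random", nstart = 3L)
  } else {
    cluster::pam(x, k, diss = diss)
  }
  unname(res$clustering)
}

# Eigenvector embedding for spectral clustering: normalized Laplacian of a
# Gaussian affinity, k smallest eigenvectors, rows normalized to unit length.
.spectral_embed <- function(d, k) {
  n <- nrow(d)
  off <- d[upper.tri(d)]
  sigma <- stats::median(off[off > 0])
  if (!length(sigma) || !is.finite(sigma) || sigma <= 0) sigma <- 1
  A <- exp(-(d / sigma)^2)
  diag(A) <- 0
  deg <- rowSums(A)
  deg[deg <= 0] <- 1e-12
  isq <- 1 / sqrt(deg)
  L <- diag(n) - (isq * A) * rep(isq, each = n)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U / norms
}

# Minimax-linkage agglomeration; returns labels at k clusters.
.minimax_cut <- function(d, k) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  # linkage between two active clusters: minimax radius of the union
  link <- function(i, j) {
    u <- c(members[[i]], members[[j]])
    min(apply(d[u, u, drop = FALSE], 1L, max))
  }
  L <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) L[i, j] <- d[i, j]
  n_active <- n
  while (n_active > k) {
    idx <- which(L == min(L), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # lexicographic
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    L[j, ] <- Inf; L[, j] <- Inf
    for (o in which(active)) {
      if (o == i) next
      v <- link(i, o)
      if (o < i) L[o, i] <- v else L[i, o] <- v
    }
    n_active <- n_active - 1L
  }
  lab <- integer(n)
  cl <- 0L
  for (i in which(active)) {
    cl <- cl + 1L
    lab[members[[i]]] <- cl
  }
  lab
}

#' Silhouette coefficient of a labelled distance matrix
#'
#' For each item, cohesion a(i) is its mean distance to the other members of
#' its cluster and separation b(i) the smallest mean distance to another
#' cluster; the silhouette value is (b - a) / max(a, b) (0 for singletons,
#' and 0 where a = b = 0).  The coefficient is the mean over items.
#'
#' @param distmat a \code{tree_dist}, \code{dist} or symmetric matrix.
#' @param labels cluster label per item (>= 2 nonempty clusters).
#' @param per_item return the per-item silhouette values instead?
#' @return the mean silhouette (or the per-item vector), in [-1, 1].
#' @export
silhouette_coefficient <- function(distmat, labels, per_item = FALSE) {
  d <- .as_dmat(distmat)
  n <- nrow(d)
  if (length(labels) != n) stop("labels must match the matrix dimension")
  labs <- unique(labels)
  if (length(labs) < 2L)
    stop("the silhouette coefficient is undefined for a single cluster")
  s <- numeric(n)
  sizes <- table(factor(labels, levels = labs))
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[match(own, labs)]] == 1L) { s[i] <- 0; next }
    a <- mean(d[i, labels == own & seq_len(n) != i])
    b <- min(vapply(labs[labs != own],
                    function(l) mean(d[i, labels == l]), numeric(1L)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  if (per_item) s else mean(s)
}

#' Variation of information between two clusterings
#'
#' VI = H(C1) + H(C2) - 2 I(C1; C2) in bits, from the joint label
#' contingency table.  A metric on partitions; 0 iff the partitions are
#' identical.
#'
#' @param c1,c2 label vectors over the same items, or
#'   \code{tree_clustering} objects.
#' @return nonnegative VI in bits.
#' @examples
#' variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 2 bits
#' @export
variation_of_information <- function(c1, c2) {
  if (inherits(c1, "tree_clustering")) c1 <- c1$labels
  if (inherits(c2, "tree_clustering")) c2 <- c2$labels
  if (length(c1) != length(c2))
    stop("clusterings must cover the same item set")
  p <- table(c1, c2) / length(c1)
  hj <- -sum(.xlog2(p))
  h1 <- -sum(.xlog2(rowSums(p)))
  h2 <- -sum(.xlog2(colSums(p)))
  max(0, 2 * hj - h1 - h2)
}

#' Select the best clustering by silhouette
#'
#' Evaluates every combination of method and k, and returns the clustering
#' with the highest silhouette coefficient.  Ties prefer the smallest k,
#' then the earlier method in \code{methods}.  The structure category uses
#' the conventional thresholds (> 0.7 strong, > 0.5 reasonable, > 0.25
#' weak, otherwise none); when the best coefficient is below 0.5 the result
#' is additionally flagged \code{single_cluster}, since structure below
#' "reasonable" is best reported as a single cluster.
#'
#' @param distmat a \code{tree_dist}, \code{dist} or symmetric matrix.
#' @param methods methods to try, in preference order.
#' @param k_range candidate cluster counts (subset of 2..n-1).
#' @param seed seed passed to each method.
#' @return a \code{tree_clustering} with an extra \code{single_cluster}
#'   flag and a \code{grid} data frame of all evaluated combinations.
#' @export
best_clustering <- function(distmat, methods = .cluster_methods,
                            k_range = NULL, seed = 1L) {
  d <- .as_dmat(distmat)
  n <- nrow(d)
  if (is.null(k_range)) k_range <- 2L:min(10L, n - 1L)
  if (any(k_range < 2L | k_range > n - 1L))
    stop("k_range must lie within [2, n-1]")
  # evaluation order implements the tie-break: lowest k first, then the
  # methods in their given preference order
  grid <- expand.grid(method = methods, k = sort(k_range),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  best <- NULL
  sils <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cl <- cluster_trees(d, grid$method[g], grid$k[g], seed = seed)
    sils[g] <- cl$silhouette
    if (is.null(best) || cl$silhouette > best$silhouette + 1e-12) best <- cl
  }
  grid$silhouette <- sils
  best$single_cluster <- best$silhouette < 0.5
  best$grid <- grid
  best
}

#' @export
print.tree_clustering <- function(x, ...) {
  cat("Tree clustering: ", x$method, ", k = ", x$k, "\n", sep = "")
  cat("  silhouette coefficient: ", round(x$silhouette, 4),
      " (", x$category, " structure)\n", sep = "")
  if (isTRUE(x$single_cluster))
    cat("  below 'reasonable' structure: treat as a single cluster\n")
  cat("  cluster sizes: ",
      paste(table(x$labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}
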