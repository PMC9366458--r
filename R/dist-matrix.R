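#' Pairwise distance matrix for a set of trees
#'
#' Computes all pairwise distances among \code{trees} under one metric.
#' Per-tree decompositions (splits, vectors, quartet statuses) are cached so
#' each tree is processed once.  With \code{dedup = TRUE}, identical
#' topologies are first collapsed to one representative; the result then
#' covers unique topologies and records multiplicities so the full set can
#' be reconstituted.
#'
#' @param trees a \code{multiPhylo} or list of \code{phylo} trees (>= 2)
#'   sharing one leaf set.
#' @param metric metric name (see \code{\link{tree_distance}}).
#' @param normalized logical; for the quartet metric, divide by
#'   choose(n, 4).  Not defined for other metrics.
#' @param dedup collapse identical topologies first?
#' @param ids optional tree identifiers (default \code{tree_1..tree_m}).
#' @return an object of class \code{tree_dist}: a list with elements
#'   \code{d} (symmetric matrix), \code{metric}, \code{normalized},
#'   \code{ids}, and, when deduplicated, \code{multiplicity} and \code{map}
#'   (index of each input tree's representative).
#' @examples
#' set.seed(1)
#' td <- distance_matrix(random_trees(5, 8), "cid")
#' round(as.matrix(td), 2)
#' @export
distance_matrix <- function(trees, metric = "cid", normalized = FALSE,
                            dedup = FALSE, ids = NULL) {
  metric <- .canon_metric(metric)
  if (metric == "ms")
    stop("matching-split information scoring is not implemented")
  if (normalized && metric != "quartet")
    stop("normalization is only defined for the quartet metric")
  m <- length(trees)
  if (m < 2L) stop("need at least 2 trees")
  if (is.null(ids)) ids <- sprintf("tree_%d", seq_len(m))
  prof <- lapply(trees, .profile)
  bad <- which(!vapply(prof, function(p)
    identical(p$labels, prof[[1L]]$labels), logical(1L)))
  if (length(bad))
    stop("trees with differing leaf sets: ",
         paste(ids[bad], collapse = ", "))
  n <- prof[[1L]]$n
  if (metric %in% c("cid", "pid", "quartet") && n < 4L)
    stop("metric '", metric, "' requires n >= 4 leaves")
  if (metric == "kc" && !all(vapply(prof, `[[`, logical(1L), "rooted")))
    stop("the KC metric requires every tree to be rooted")

  multiplicity <- NULL
  map <- NULL
  if (dedup) {
    key <- vapply(prof, function(p) {
      k <- sort(.split_keys(.splits_logical(p)))
      base <- paste(k, collapse = ";")
      if (metric == "kc") {  # rooted topology identity for the rooted metric
        ck <- sort(.split_keys(p$M[p$internal, , drop = FALSE]))
        base <- paste(base, paste(ck, collapse = ";"), sep = "#")
      }
      base
    }, character(1L))
    rep_idx <- match(key, key)
    uniq <- which(rep_idx == seq_len(m))
    map <- match(rep_idx, uniq)
    multiplicity <- as.vector(table(factor(map, levels = seq_along(uniq))))
    prof <- prof[uniq]
    ids_full <- ids
    ids <- ids[uniq]
    m <- length(prof)
  }

  feat <- switch(metric,
    rf = lapply(prof, function(p) .split_keys(.splits_logical(p))),
    cid = lapply(prof, .cid_features),
    pid = lapply(prof, .pid_features),
    quartet = {
      combs <- .quartet_combs(n)
      lapply(prof, function(p) .quartet_status(.path_matrix(p), combs))
    },
    path = lapply(prof, function(p) .ut(.path_matrix(p))),
    kc = lapply(prof, function(p) .ut(.mrca_depth(p))),
    sv = lapply(prof, function(p) .ut(.sv_matrix(p))))

  pairfun <- switch(metric,
    rf = .d_rf,
    cid = function(a, b) .d_info(a, b, "cid"),
    pid = function(a, b) .d_info(a, b, "pid"),
    quartet = function(a, b) sum(a != b),
    function(a, b) sqrt(sum((a - b)^2)))

  d <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1L)) {
    fi <- feat[[i]]
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <- pairfun(fi, feat[[j]])
    }
  }
  if (normalized) d <- d / choose(n, 4L)

  out <- list(d = d, metric = metric, normalized = normalized, ids = ids,
              n_leaves = n)
  if (dedup) {
    out$multiplicity <- multiplicity
    out$map <- map
    out$full_ids <- ids_full
  }
  class(out) <- "tree_dist"
  out
}

# Accept a tree_dist, matrix or dist and return a validated matrix.
.as_dmat <- function(x) {
  d <- if (inherits(x, "tree_dist")) x$d
       else if (inherits(x, "dist")) as.matrix(x)
       else as.matrix(x)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be nonnegative")
  d
}

#' @export
as.matrix.tree_dist <- function(x, ...) x$d

#' @export
as.dist.tree_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' @export
print.tree_dist <- function(x, ...) {
  cat("Tree distance matrix (", x$metric,
      if (x$normalized) ", normalized" else "", ")\n", sep = "")
  cat("  ", nrow(x$d), " trees, ", x$n_leaves, " leaves\n", sep = "")
  if (!is.null(x$multiplicity))
    cat("  deduplicated topologies; multiplicities ",
        paste(x$multiplicity, collapse = ", "), "\n", sep = "")
  rng <- range(x$d[upper.tri(x$d)])
  cat("  distance range: ", signif(rng[1L], 4), " - ",
      signif(rng[2L], 4), "\n", sep = "")
  invisible(x)
}
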