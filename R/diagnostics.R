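# How faithfully does an embedding represent the original tree space?

# Neighbour ranks: R[i, j] = rank of j among i's neighbours by distance,
# ties broken by item index for reproducibility.
.neighbor_ranks <- function(d) {
  n <- nrow(d)
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    o <- order(d[i, ], seq_len(n))
    o <- o[o != i]
    R[i, o] <- seq_len(n - 1L)
  }
  R
}

.emb_dmat <- function(embedding) {
  pts <- if (inherits(embedding, "tree_map")) embedding$points
         else as.matrix(embedding)
  as.matrix(stats::dist(pts))
}

#' Trustworthiness and continuity of a mapping
#'
#' Rank-based [0, 1] scores of neighbourhood preservation with k nearest
#' neighbours.  Trustworthiness penalises points that enter the mapped
#' k-neighbourhood without being original k-neighbours, weighted by their
#' original rank excess; continuity symmetrically penalises original
#' neighbours expelled from the mapped neighbourhood, weighted by mapped
#' rank excess.  Both use the standard normalisation, so 1 means perfect
#' neighbourhood preservation; their product is a composite quality score.
#'
#' @param distmat original distances (\code{tree_dist}, \code{dist} or
#'   matrix).
#' @param embedding a \code{tree_map} or coordinate matrix.
#' @param k neighbourhood size, k < n/2 (default 10).
#' @return list with \code{trustworthiness}, \code{continuity},
#'   \code{product} and \code{k}.
#' @export
trustworthiness_continuity <- function(distmat, embedding, k = 10L) {
  d <- .as_dmat(distmat)
  n <- nrow(d)
  if (k >= n / 2) stop("k must be smaller than n/2")
  dm <- .emb_dmat(embedding)
  if (nrow(dm) != n) stop("embedding size does not match the distances")
  Ro <- .neighbor_ranks(d)
  Rm <- .neighbor_ranks(dm)
  tsum <- 0
  csum <- 0
  for (i in seq_len(n)) {
    in_map <- Rm[i, ] >= 1L & Rm[i, ] <= k
    in_orig <- Ro[i, ] >= 1L & Ro[i, ] <= k
    U <- which(in_map & !in_orig)
    V <- which(in_orig & !in_map)
    if (length(U)) tsum <- tsum + sum(Ro[i, U] - k)
    if (length(V)) csum <- csum + sum(Rm[i, V] - k)
  }
  norm <- 2 / (n * k * (2 * n - 3 * k - 1))
  t_val <- 1 - norm * tsum
  c_val <- 1 - norm * csum
  list(trustworthiness = t_val, continuity = c_val,
       product = t_val * c_val, k = as.integer(k))
}

#' Shepard-plot correlations between original and mapped distances
#'
#' Pearson r^2 and Kendall's tau over all unordered pairs: r^2 is 1 when the
#' ratio of any two distances is preserved (scale-free), 0 when mapped
#' distances are unrelated to the originals; tau is 1 when pair rankings
#' agree.
#'
#' @inheritParams trustworthiness_continuity
#' @return list with \code{pearson_r2}, \code{kendall_tau} and a
#'   \code{degenerate} flag (constant mapped distances give r^2 = 0).
#' @export
distance_correlations <- function(distmat, embedding) {
  d <- .as_dmat(distmat)
  if (nrow(d) < 3L) stop("need at least 3 items")
  dm <- .emb_dmat(embedding)
  x <- d[upper.tri(d)]
  y <- dm[upper.tri(dm)]
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(list(pearson_r2 = 0, kendall_tau = NA_real_, degenerate = TRUE))
  }
  list(pearson_r2 = stats::cor(x, y)^2,
       kendall_tau = stats::cor(x, y, method = "kendall"),
       degenerate = FALSE)
}

#' Minimum spanning tree of a distance matrix
#'
#' Prim's algorithm with a deterministic lexicographic tie-break.
#'
#' @param distmat a \code{tree_dist}, \code{dist} or symmetric matrix with
#'   finite entries.
#' @return an (n-1) x 2 matrix of edges (i < j).
#' @examples
#' mst_edges(as.matrix(dist(c(0, 1, 3))))
#' @export
mst_edges <- function(distmat) {
  d <- .as_dmat(distmat)
  n <- nrow(d)
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best <- d[1L, ]
  best_from <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[order(best[cand], cand)][1L]
    i <- best_from[j]
    edges[e, ] <- c(min(i, j), max(i, j))
    in_tree[j] <- TRUE
    upd <- which(!in_tree & d[j, ] < best)
    best[upd] <- d[j, upd]
    best_from[upd] <- j
  }
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

#' Minimum spanning tree extension factor of a mapping
#'
#' The total mapped length of the MST computed from the *original*
#' distances, divided by the length of the MST computed from the mapped
#' distances (the shortest possible mapped spanning length).  Unity in the
#' absence of distortion; always >= 1 by optimality of the denominator.
#'
#' @inheritParams trustworthiness_continuity
#' @return a real >= 1.
#' @export
mst_extension_factor <- function(distmat, embedding) {
  d <- .as_dmat(distmat)
  dm <- .emb_dmat(embedding)
  eo <- mst_edges(d)
  em <- mst_edges(dm)
  num <- sum(dm[eo])
  den <- sum(dm[em])
  if (den == 0) return(1)
  num / den
}

#' Correlation dimension (intrinsic dimensionality)
#'
#' Estimates the scaling exponent of the pair-correlation sum
#' C(r) = 2 / (n (n - 1)) * #\{pairs with d <= r\}: the least-squares slope
#' of log C(r) against log r across log-spaced radii inside the small-radius
#' scaling window (by default between the 0.5\% and 10\% quantiles of the
#' positive off-diagonal distances, where C(r) has not yet saturated).
#'
#' @param distmat a \code{tree_dist}, \code{dist} or symmetric matrix
#'   (n >= 20 recommended).
#' @param window quantile window of positive distances over which to fit.
#' @param n_radii number of log-spaced radii evaluated.
#' @return list with \code{dimension}, \code{window} (the radius range
#'   used), \code{radii}, \code{correlation_sum} and a \code{degenerate}
#'   flag (all-identical distances give dimension 0).
#' @export
correlation_dimension <- function(distmat, window = c(0.005, 0.10),
                                  n_radii = 25L) {
  d <- .as_dmat(distmat)
  off <- d[upper.tri(d)]
  pos <- off[off > 0]
  if (!length(pos) || stats::sd(off) == 0) {
    return(list(dimension = 0, window = c(NA_real_, NA_real_),
                radii = numeric(0), correlation_sum = numeric(0),
                degenerate = TRUE))
  }
  r_lo <- stats::quantile(pos, window[1L], names = FALSE)
  r_hi <- stats::quantile(pos, window[2L], names = FALSE)
  if (r_lo <= 0) r_lo <- min(pos)
  if (r_hi <= r_lo) r_hi <- max(pos)
  radii <- exp(seq(log(r_lo), log(r_hi), length.out = n_radii))
  cs <- vapply(radii, function(r) mean(off <= r), numeric(1L))
  keep <- cs > 0
  radii <- radii[keep]
  cs <- cs[keep]
  if (length(unique(radii)) < 3L) {
    return(list(dimension = 0, window = c(r_lo, r_hi), radii = radii,
                correlation_sum = cs, degenerate = TRUE))
  }
  fit <- stats::lm(log(cs) ~ log(radii))
  list(dimension = unname(stats::coef(fit)[2L]), window = c(r_lo, r_hi),
       radii = radii, correlation_sum = cs, degenerate = FALSE)
}

#' Cumulative adjusted r^2 of a covariate on leading axes
#'
#' For each prefix of axes 1..k (k = 1..max_d), fits the covariate on those
#' axes by least squares and reports the adjusted r^2,
#' 1 - (1 - R^2)(n - 1)/(n - k - 1).  Used, e.g., to ask how much of the
#' variance in stratigraphic congruence the first few axes of a mapping
#' explain.
#'
#' @param embedding a \code{tree_map} or coordinate matrix.
#' @param covariate finite numeric vector, one value per item.
#' @param max_d number of axis prefixes (default: all axes).
#' @return numeric vector of adjusted r^2, entry k for axes 1..k.
#' @export
axis_covariate_r2 <- function(embedding, covariate, max_d = NULL) {
  pts <- if (inherits(embedding, "tree_map")) embedding$points
         else as.matrix(embedding)
  n <- nrow(pts)
  if (is.null(max_d)) max_d <- ncol(pts)
  if (max_d > ncol(pts)) stop("max_d exceeds the number of axes")
  if (length(covariate) != n || any(!is.finite(covariate)))
    stop("covariate must be finite with one value per item")
  if (n <= max_d + 1L) stop("need n > max_d + 1 items")
  vapply(seq_len(max_d), function(k) {
    fit <- stats::lm(covariate ~ pts[, seq_len(k), drop = FALSE])
    # an exact fit (e.g. covariate equal to an axis) is legitimate here
    suppressWarnings(summary(fit)$adj.r.squared)
  }, numeric(1L))
}

#' Bundle of mapping-quality diagnostics
#'
#' Computes trustworthiness and continuity (and their product), Shepard
#' correlations, the MST extension factor and, optionally, the cumulative
#' adjusted r^2 of a covariate on the leading axes.  A mapping is flagged
#' adequate when both trustworthiness and continuity exceed 0.95.
#'
#' @inheritParams trustworthiness_continuity
#' @param covariate optional numeric covariate (e.g. minimum implied gap).
#' @param max_d axis prefixes for the covariate regression.
#' @return an object of class \code{mapping_quality}.
#' @export
mapping_quality <- function(distmat, embedding, k = 10L, covariate = NULL,
                            max_d = NULL) {
  tc <- trustworthiness_continuity(distmat, embedding, k)
  sc <- distance_correlations(distmat, embedding)
  mef <- mst_extension_factor(distmat, embedding)
  out <- list(trustworthiness = tc$trustworthiness,
              continuity = tc$continuity, product = tc$product, k = tc$k,
              pearson_r2 = sc$pearson_r2, kendall_tau = sc$kendall_tau,
              mst_extension = mef,
              adequate = tc$trustworthiness > 0.95 & tc$continuity > 0.95)
  if (!is.null(covariate))
    out$covariate_adj_r2 <- axis_covariate_r2(embedding, covariate, max_d)
  class(out) <- "mapping_quality"
  out
}

#' @export
print.mapping_quality <- function(x, ...) {
  cat("Mapping quality (k = ", x$k, " neighbours)\n", sep = "")
  cat(sprintf("  trustworthiness: %.4f   continuity: %.4f   product: %.4f\n",
              x$trustworthiness, x$continuity, x$product))
  cat(sprintf("  Shepard Pearson r2: %.4f   Kendall tau: %.4f\n",
              x$pearson_r2, x$kendall_tau))
  cat(sprintf("  MST extension factor: %.3f\n", x$mst_extension))
  cat("  adequate (T and C both > 0.95): ",
      if (isTRUE(x$adequate)) "yes" else "no", "\n", sep = "")
  if (!is.null(x$covariate_adj_r2))
    cat("  covariate adjusted r2 by axis prefix: ",
        paste(round(x$covariate_adj_r2, 3), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
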