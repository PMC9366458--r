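# Dimensionality reduction of tree distance matrices.

.map_methods <- c("kruskal1", "sammon", "cca", "diffusion", "laplacian",
                  "tsne")

.new_tree_map <- function(points, method, ids, params = list(),
                          seed = NULL, eigenvalues = NULL, stress = NULL,
                          correction = FALSE, converged = TRUE) {
  rownames(points) <- ids
  colnames(points) <- sprintf("axis_%d", seq_len(ncol(points)))
  structure(list(points = points, method = method, ndim = ncol(points),
                 params = params, seed = seed, eigenvalues = eigenvalues,
                 stress = stress, correction = correction,
                 converged = converged),
            class = "tree_map")
}

.map_ids <- function(distmat, d) {
  if (inherits(distmat, "tree_dist")) distmat$ids
  else if (!is.null(rownames(d))) rownames(d)
  else sprintf("item_%d", seq_len(nrow(d)))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres the squared distances and extracts coordinates from the
#' top eigenvectors.  If the spectrum has a materially negative eigenvalue
#' (the metric is not Euclidean-embeddable), the Cailliez additive-constant
#' correction is applied to all off-diagonal distances first; this is
#' recorded in the result.  Axes are ordered by non-increasing eigenvalue.
#'
#' @param distmat a \code{tree_dist}, \code{dist} or symmetric matrix.
#' @param ndim number of axes, 1 <= ndim <= n - 1.
#' @return a \code{tree_map} with per-axis eigenvalues, the additive
#'   constant used (\code{params$additive_constant}) and a
#'   \code{correction} flag.
#' @examples
#' x <- seq_len(10)
#' pc <- pcoa(as.matrix(dist(x)), 2)
#' round(pc$eigenvalues[1:3], 6)
#' @export
pcoa <- function(distmat, ndim = 2L) {
  d <- .as_dmat(distmat)
  n <- nrow(d)
  if (ndim < 1L || ndim > n - 1L) stop("ndim must be in [1, n-1]")
  # cmdscale warns when fewer than ndim eigenvalues are positive; the
  # missing axes are padded with zero coordinates below
  res <- suppressWarnings(stats::cmdscale(d, k = ndim, eig = TRUE))
  correction <- FALSE
  ac <- 0
  tol <- 1e-8 * max(abs(res$eig), 1e-300)
  if (min(res$eig) < -tol) {
    res <- suppressWarnings(stats::cmdscale(d, k = ndim, eig = TRUE,
                                            add = TRUE))
    correction <- TRUE
    ac <- res$ac
  }
  pts <- res$points
  if (ncol(pts) < ndim) {  # degenerate spectra yield fewer axes; pad zeros
    pts <- cbind(pts, matrix(0, n, ndim - ncol(pts)))
  }
  .new_tree_map(pts, "pcoa", .map_ids(distmat, d),
                params = list(additive_constant = ac),
                eigenvalues = res$eig, correction = correction)
}

#' Map a tree space into few dimensions
#'
#' Six mapping methods besides \code{\link{pcoa}}: non-metric MDS with the
#' Kruskal-1 stress (\code{"kruskal1"}), Sammon's metric non-linear mapping
#' (\code{"sammon"}), curvilinear components analysis (\code{"cca"}),
#' diffusion mapping (\code{"diffusion"}), Laplacian eigenmapping over a
#' nearest-neighbour graph (\code{"laplacian"}, 50 neighbours by default)
#' and exact t-SNE (\code{"tsne"}, at most 3 output dimensions).  Iterative
#' methods start from the PCoA configuration unless
#' \code{params$init} supplies one, and record their final stress or
#' objective; all methods are deterministic given \code{seed}.
#'
#' @param distmat a \code{tree_dist}, \code{dist} or symmetric matrix.
#' @param method one of \code{"kruskal1"}, \code{"sammon"}, \code{"cca"},
#'   \code{"diffusion"}, \code{"laplacian"}, \code{"tsne"}.
#' @param ndim number of output dimensions (>= 1; n >= ndim + 2).
#' @param params optional method parameters: \code{init} (matrix),
#'   \code{maxit}, \code{tol}, \code{perplexity}, \code{n_neighbors},
#'   \code{epsilon}, \code{n_epochs}.
#' @param seed integer seed.
#' @return a \code{tree_map}.
#' @export
map_space <- function(distmat, method = .map_methods, ndim = 2L,
                      params = list(), seed = 1L) {
  method <- match.arg(method)
  d <- .as_dmat(distmat)
  n <- nrow(d)
  if (ndim < 1L) stop("ndim must be >= 1")
  if (method == "tsne" && ndim > 3L)
    stop("t-SNE mappings support at most 3 dimensions")
  if (n < ndim + 2L) stop("need at least ndim + 2 items")
  if (!is.null(seed)) set.seed(seed)
  ids <- .map_ids(distmat, d)
  init <- params$init
  if (is.null(init)) init <- pcoa(d, ndim)$points
  init <- as.matrix(init)[, seq_len(ndim), drop = FALSE]
  res <- switch(method,
    kruskal1 = .map_kruskal1(d, ndim, init, params),
    sammon = .map_sammon(d, ndim, init, params),
    cca = .map_cca(d, ndim, init, params),
    diffusion = .map_diffusion(d, ndim, params),
    laplacian = .map_laplacian(d, ndim, params),
    tsne = .map_tsne(d, ndim, init, params))
  .new_tree_map(res$points, method, ids, params = res$params, seed = seed,
                eigenvalues = res$eigenvalues, stress = res$stress,
                converged = res$converged)
}

# Strictly positive copy of the dissimilarities for MASS optimisers, which
# reject zero distances between distinct items (duplicate topologies).
.positive_d <- function(d) {
  off <- d[upper.tri(d)]
  if (all(off > 0)) return(d)
  eps <- if (any(off > 0)) min(off[off > 0]) * 1e-3 else 1e-6
  d[d <= 0] <- eps
  diag(d) <- 0
  d
}

.jitter_dups <- function(y) {
  dup <- duplicated(round(y, 12L))
  if (any(dup)) {
    y[dup, ] <- y[dup, , drop = FALSE] +
      matrix(rnorm(sum(dup) * ncol(y), sd = 1e-8), sum(dup))
  }
  y
}

.map_kruskal1 <- function(d, ndim, init, params) {
  maxit <- params$maxit %||% 500L
  tol <- params$tol %||% 1e-6
  dp <- .positive_d(d)
  init <- .jitter_dups(init)
  res <- MASS::isoMDS(stats::as.dist(dp), y = init, k = ndim,
                      maxit = maxit, tol = tol, trace = FALSE)
  list(points = res$points, stress = res$stress / 100,  # Kruskal-1 fraction
       params = list(maxit = maxit, tol = tol), converged = TRUE,
       eigenvalues = NULL)
}

.map_sammon <- function(d, ndim, init, params) {
  maxit <- params$maxit %||% 500L
  tol <- params$tol %||% 1e-6
  dp <- .positive_d(d)
  init <- .jitter_dups(init)
  res <- MASS::sammon(stats::as.dist(dp), y = init, k = ndim,
                      niter = maxit, tol = tol, trace = FALSE)
  list(points = res$points, stress = res$stress,
       params = list(maxit = maxit, tol = tol), converged = TRUE,
       eigenvalues = NULL)
}

# Curvilinear components analysis (Demartines & Herault): online updates
# that preserve distances that are short *in the mapping*, with a
# neighbourhood radius shrinking geometrically between quantiles of the
# mapped distances.
.map_cca <- function(d, ndim, init, params) {
  n <- nrow(d)
  epochs <- params$n_epochs %||% 50L
  alpha0 <- params$alpha %||% 0.5
  y <- .jitter_dups(init)
  dy0 <- as.matrix(stats::dist(y))
  off <- dy0[upper.tri(dy0)]
  off <- off[off > 0]
  if (!length(off)) off <- 1
  lam0 <- stats::quantile(off, 0.9)
  lam1 <- max(stats::quantile(off, 0.1), 1e-12)
  for (ep in seq_len(epochs)) {
    lambda <- lam0 * (lam1 / lam0)^((ep - 1) / max(1, epochs - 1))
    alpha <- alpha0 * (1 - (ep - 1) / epochs)
    for (i in sample.int(n)) {
      diffs <- sweep(y, 2L, y[i, ])          # y_j - y_i
      dy <- sqrt(rowSums(diffs^2))
      sel <- which(dy > 0 & dy < lambda & seq_len(n) != i)
      if (!length(sel)) next
      fac <- alpha * (d[i, sel] - dy[sel]) / dy[sel]
      y[sel, ] <- y[sel, , drop = FALSE] + fac * diffs[sel, , drop = FALSE]
    }
  }
  dy <- as.matrix(stats::dist(y))
  w <- dy < lam1
  stress <- sum(((d - dy)^2 * w)[upper.tri(d)]) / 2
  list(points = y, stress = stress,
       params = list(n_epochs = epochs, lambda_range = c(lam0, lam1)),
       converged = TRUE, eigenvalues = NULL)
}

# Diffusion map: Markov transition matrix over a Gaussian kernel graph;
# coordinates are the leading nontrivial eigenvectors scaled by their
# eigenvalues.
.map_diffusion <- function(d, ndim, params) {
  n <- nrow(d)
  off <- d[upper.tri(d)]
  eps <- params$epsilon %||% (2 * stats::median(off)^2)
  if (!is.finite(eps) || eps <= 0) eps <- 1
  K <- exp(-d^2 / eps)
  deg <- rowSums(K)
  isq <- 1 / sqrt(deg)
  S <- (isq * K) * rep(isq, each = n)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  psi <- isq * ev$vectors  # right eigenvectors of the Markov matrix
  take <- seq_len(ndim) + 1L
  lam <- ev$values[take]
  pts <- sweep(psi[, take, drop = FALSE], 2L, lam, `*`)
  pts <- .fix_signs(pts)
  list(points = pts, stress = NULL,
       params = list(epsilon = eps), converged = TRUE,
       eigenvalues = ev$values)
}

# Laplacian eigenmap: symmetrised unweighted kNN graph, generalized
# eigenvectors of the graph Laplacian (smallest nontrivial).
.map_laplacian <- function(d, ndim, params) {
  n <- nrow(d)
  k <- min(params$n_neighbors %||% 50L, n - 1L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    o <- order(d[i, ], seq_len(n))
    o <- o[o != i][seq_len(k)]
    A[i, o] <- 1
  }
  A <- pmax(A, t(A))  # mutual or one-sided neighbours both connect
  deg <- rowSums(A)
  deg[deg <= 0] <- 1e-12
  isq <- 1 / sqrt(deg)
  Lsym <- diag(n) - (isq * A) * rep(isq, each = n)
  ev <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  take <- n - 1L - seq_len(ndim) + 1L  # skip the constant eigenvector
  pts <- isq * ev$vectors[, take, drop = FALSE]
  pts <- .fix_signs(pts)
  list(points = pts, stress = NULL,
       params = list(n_neighbors = k), converged = TRUE,
       eigenvalues = rev(ev$values))
}

# Exact t-SNE with PCoA initialisation.  Classic schedule: early
# exaggeration 4 for the first 100 iterations, learning rate 100 with
# adaptive per-coordinate gains, momentum 0.5 then 0.8 after iteration 250.
.map_tsne <- function(d, ndim, init, params) {
  n <- nrow(d)
  perplexity <- min(params$perplexity %||% 30, (n - 1) / 3)
  maxit <- params$maxit %||% 1000L
  eta <- params$eta %||% 100
  exaggeration <- params$exaggeration %||% 4
  stop_lying <- params$stop_lying %||% 100L
  P <- .tsne_p(d, perplexity)
  # retain the PCoA configuration, scaled small per standard practice
  y <- init - rep(colMeans(init), each = n)
  sdy <- max(stats::sd(as.vector(y)), 1e-12)
  y <- y / sdy * 1e-4
  inc <- matrix(0, n, ndim)
  gains <- matrix(1, n, ndim)
  for (it in seq_len(maxit)) {
    Pt <- if (it <= stop_lying) P * exaggeration else P
    mom <- if (it <= 250L) 0.5 else 0.8
    sq <- as.matrix(stats::dist(y))^2
    Q <- 1 / (1 + sq)
    diag(Q) <- 0
    Z <- sum(Q)
    Qn <- pmax(Q / Z, 1e-12)
    W <- (Pt - Qn) * Q
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(inc),
                               gains + 0.2, gains * 0.8))
    inc <- mom * inc - eta * gains * grad
    y <- y + inc
    y <- y - rep(colMeans(y), each = n)
  }
  sq <- as.matrix(stats::dist(y))^2
  Q <- 1 / (1 + sq)
  diag(Q) <- 0
  Qn <- pmax(Q / sum(Q), 1e-12)
  kl <- sum(P[P > 0] * log(P[P > 0] / Qn[P > 0]))
  list(points = y, stress = kl,
       params = list(perplexity = perplexity, maxit = maxit, eta = eta,
                     exaggeration = exaggeration),
       converged = TRUE, eigenvalues = NULL)
}

# Symmetrised input probabilities at a given perplexity (binary search on
# the per-point bandwidth).
.tsne_p <- function(d, perplexity) {
  n <- nrow(d)
  sq <- d^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- sq[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in seq_len(64L)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { h <- 0; p <- rep(1 / length(di), length(di)) }
      else {
        p <- p / sp
        h <- -sum(.xlog2(p)) * log(2)  # entropy in nats
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Deterministic sign convention for eigenvector coordinates.
.fix_signs <- function(pts) {
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  pts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tree_map <- function(x, ...) {
  cat("Tree space mapping: ", x$method, ", ", nrow(x$points), " items in ",
      x$ndim, " dimensions\n", sep = "")
  if (!is.null(x$stress))
    cat("  final stress/objective: ", signif(x$stress, 5), "\n", sep = "")
  if (isTRUE(x$correction))
    cat("  additive-constant (Cailliez) correction applied\n")
  if (!isTRUE(x$converged))
    cat("  warning: not converged within the iteration cap\n")
  invisible(x)
}

#' @export
plot.tree_map <- function(x, axes = c(1L, 2L), col = 1, pch = 16, ...) {
  if (x$ndim == 1L) {
    plot(x$points[, 1L], rep(0, nrow(x$points)), xlab = "axis 1",
         ylab = "", col = col, pch = pch, ...)
    return(invisible(x))
  }
  # equal axis scales: mapped distances are only meaningful at 1:1 aspect
  plot(x$points[, axes[1L]], x$points[, axes[2L]], asp = 1,
       xlab = sprintf("axis %d", axes[1L]),
       ylab = sprintf("axis %d", axes[2L]), col = col, pch = pch, ...)
  invisible(x)
}
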