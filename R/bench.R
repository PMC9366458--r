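# Metric benchmarks on uniformly sampled topologies, and the end-to-end
# analysis pipeline.

# Features of one random parent-array tree, computed once per tree.
.bench_features <- function(pt, n, want, utmask, combs = NULL) {
  pr <- .profile_core(pt$parent, pt$root, n, seq_len(n), NULL)
  out <- list()
  D <- NULL
  if (any(c("kc", "path", "tci") %in% want)) {
    D <- .mrca_depth(pr)
    if ("tci" %in% want) out$tci <- sum(D[utmask])
    if ("kc" %in% want) out$kc <- D[utmask]
  }
  P <- NULL
  if (any(c("path", "quartet") %in% want)) {
    P <- .path_matrix(pr, D)
    if ("path" %in% want) out$path <- P[utmask]
    if ("quartet" %in% want) out$quartet <- .quartet_status(P, combs)
  }
  if (any(c("rf", "sv", "cid", "pid") %in% want)) {
    S <- .splits_logical(pr)
    if ("rf" %in% want) out$rf <- .split_keys(S)
    if ("sv" %in% want) out$sv <- .sv_matrix(pr, S)[utmask]
    if ("cid" %in% want) out$cid <- .cid_features(pr, S)
    if ("pid" %in% want) out$pid <- .pid_features(pr, S)
  }
  out
}

.bench_pair_dist <- function(f1, f2, metric) {
  switch(metric,
    rf = .d_rf(f1$rf, f2$rf),
    cid = .d_info(f1$cid, f2$cid, "cid"),
    pid = .d_info(f1$pid, f2$pid, "pid"),
    quartet = sum(f1$quartet != f2$quartet),
    path = sqrt(sum((f1$path - f2$path)^2)),
    kc = sqrt(sum((f1$kc - f2$kc)^2)),
    sv = sqrt(sum((f1$sv - f2$sv)^2)))
}

.new_bench_result <- function(...) structure(list(...), class = "bench_result")

#' Balance-independence benchmark of a tree metric
#'
#' Draws \code{n_pairs} independent pairs of rooted binary trees uniformly
#' from all labelled topologies, computes each requested metric distance per
#' pair (unrooted metrics see deterministically unrooted copies, so every
#' metric scores the identical topological sample) and the absolute
#' difference of the trees' total cophenetic indices, and reports the
#' squared Pearson correlation between distance and |delta TCI|.  A low r^2
#' means the metric is insensitive to differences in tree balance.
#'
#' @param metrics metric names (any of rf, cid, pid, quartet, path, kc, sv).
#' @param n_pairs number of tree pairs (default 10000).
#' @param n_leaves leaves per tree (default 25).
#' @param seed integer seed.
#' @return a \code{bench_result} (single metric) or named list of them:
#'   each records the test, metric, sample size, seed, the r^2 statistic and
#'   a degeneracy flag (constant distances give r^2 = 0).
#' @examples
#' balance_independence("rf", n_pairs = 200, n_leaves = 10, seed = 1)
#' @export
balance_independence <- function(metrics = c("rf", "cid", "path", "kc",
                                             "sv"),
                                 n_pairs = 10000L, n_leaves = 25L,
                                 seed = NULL) {
  metrics <- vapply(metrics, .canon_metric, character(1L), USE.NAMES = FALSE)
  if ("ms" %in% metrics)
    stop("matching-split information scoring is not implemented")
  if (!is.null(seed)) set.seed(seed)
  want <- c(metrics, "tci")
  utmask <- upper.tri(matrix(0L, n_leaves, n_leaves))
  combs <- if ("quartet" %in% metrics) .quartet_combs(n_leaves) else NULL
  dmat <- matrix(0, n_pairs, length(metrics),
                 dimnames = list(NULL, metrics))
  dtci <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    f1 <- .bench_features(.rtopo_parent(n_leaves), n_leaves, want, utmask,
                          combs)
    f2 <- .bench_features(.rtopo_parent(n_leaves), n_leaves, want, utmask,
                          combs)
    dtci[p] <- abs(f1$tci - f2$tci)
    for (m in seq_along(metrics))
      dmat[p, m] <- .bench_pair_dist(f1, f2, metrics[m])
  }
  out <- lapply(metrics, function(m) {
    x <- dmat[, m]
    degenerate <- stats::sd(x) == 0 || stats::sd(dtci) == 0
    r2 <- if (degenerate) 0 else stats::cor(x, dtci)^2
    .new_bench_result(test = "balance_independence", metric = m,
                      n_pairs = n_pairs, n_leaves = n_leaves, seed = seed,
                      statistic = r2, statistic_name = "r_squared",
                      degenerate = degenerate)
  })
  names(out) <- metrics
  if (length(out) == 1L) out[[1L]] else out
}

#' Saturation benchmark of a tree metric
#'
#' Draws \code{n_pairs} independent pairs of unrooted binary trees uniformly
#' from all labelled topologies and counts how many pairs attain the
#' maximum possible distance (within a 1e-9 relative tolerance for
#' real-valued metrics).  The maximum is 2(n-3) for RF, choose(n, 4) for
#' the quartet distance and, for the information distances, the per-pair
#' bound H(T1) + H(T2) (no information shared).  A metric that saturates
#' easily cannot discriminate among very different trees.
#'
#' @param metric one of \code{"rf"}, \code{"quartet"}, \code{"cid"},
#'   \code{"pid"} (metrics with a defined attainable maximum).
#' @param n_pairs number of pairs (default 100000).
#' @param n_leaves leaves per tree (default 11).
#' @param seed integer seed.
#' @return a \code{bench_result} with the count at maximum
#'   (\code{statistic}), the saturation rate, and the maximum used.
#' @examples
#' saturation_test("rf", n_pairs = 500, n_leaves = 11, seed = 1)
#' @export
saturation_test <- function(metric = "rf", n_pairs = 100000L,
                            n_leaves = 11L, seed = NULL) {
  metric <- .canon_metric(metric)
  if (!metric %in% c("rf", "quartet", "cid", "pid"))
    stop("metric '", metric, "' has no defined attainable maximum")
  if (!is.null(seed)) set.seed(seed)
  utmask <- upper.tri(matrix(0L, n_leaves, n_leaves))
  combs <- if (metric == "quartet") .quartet_combs(n_leaves) else NULL
  count <- 0L
  max_desc <- switch(metric,
    rf = 2 * (n_leaves - 3),
    quartet = choose(n_leaves, 4L),
    "per-pair H(T1) + H(T2)")
  for (p in seq_len(n_pairs)) {
    f1 <- .bench_features(.utopo_parent(n_leaves), n_leaves, metric, utmask,
                          combs)
    f2 <- .bench_features(.utopo_parent(n_leaves), n_leaves, metric, utmask,
                          combs)
    hit <- switch(metric,
      rf = length(intersect(f1$rf, f2$rf)) == 0L,
      quartet = all(f1$quartet != f2$quartet),
      cid = , pid = {
        f1m <- f1[[metric]]; f2m <- f2[[metric]]
        dmax <- f1m$H + f2m$H
        dmax > 0 &&
          .d_info(f1m, f2m, metric) >= dmax * (1 - 1e-9)
      })
    if (hit) count <- count + 1L
  }
  .new_bench_result(test = "saturation", metric = metric, n_pairs = n_pairs,
                    n_leaves = n_leaves, seed = seed, statistic = count,
                    statistic_name = "pairs_at_maximum",
                    rate = count / n_pairs, maximum = max_desc,
                    rooted = FALSE)
}

#' @export
print.bench_result <- function(x, ...) {
  cat("Benchmark: ", x$test, " (", x$metric, ")\n", sep = "")
  cat("  ", x$n_pairs, " pairs of ", x$n_leaves, "-leaf trees",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  cat("  ", x$statistic_name, ": ", format(x$statistic, digits = 6),
      "\n", sep = "")
  if (!is.null(x$rate))
    cat("  saturation rate: ", signif(x$rate, 5), "\n", sep = "")
  if (isTRUE(x$degenerate)) cat("  (degenerate: constant distances)\n")
  invisible(x)
}

#' Run the full tree-space pipeline
#'
#' Orchestrates: optional posterior subsampling, distance matrix
#' construction, silhouette-selected clustering, mappings into 1..d_max
#' dimensions, distortion diagnostics per mapping and, when stratigraphic
#' ranges are supplied, minimum-implied-gap scoring with per-axis
#' regressions.  Each stage fails with a message naming the stage; partial
#' results computed before a failure are retained in the returned report.
#'
#' @param trees a \code{multiPhylo}, list of trees, or path to a tree file.
#' @param metric tree distance metric.
#' @param d_max largest mapping dimension (1-12).
#' @param map_methods mapping methods to run besides PCoA.
#' @param cluster_methods clustering methods for model selection.
#' @param ranges optional stratigraphic ranges (data frame or TSV path).
#' @param subsample optional list(burnin_fraction, target_count) for
#'   posterior subsampling.
#' @param k neighbourhood size for trustworthiness/continuity.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @param seed integer seed.
#' @return a report list of class \code{treespace_report}.
#' @export
analyze_trees <- function(trees, metric = "cid", d_max = 3L,
                          map_methods = character(0L),
                          cluster_methods = .cluster_methods,
                          ranges = NULL, subsample = NULL, k = 10L,
                          out_dir = NULL, seed = 1L) {
  if (d_max < 1L || d_max > 12L) stop("d_max must be in 1..12")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (is.character(trees)) trees <- stage("read", read_trees(trees))
  if (!is.null(subsample))
    trees <- stage("subsample", subsample_posterior(
      trees, subsample$burnin_fraction %||% 0.5,
      subsample$target_count %||% 2500L))
  report <- list(metric = .canon_metric(metric), n_trees = length(trees),
                 seed = seed, d_max = d_max)
  class(report) <- "treespace_report"
  td <- stage("distances", distance_matrix(trees, metric))
  report$distances <- td
  report$clustering <- stage("clustering",
    best_clustering(td, methods = cluster_methods, seed = seed))
  n <- length(trees)
  kk <- min(k, max(1L, floor((n - 1) / 2)))
  maps <- list()
  quality <- list()
  for (dd in seq_len(d_max)) {
    if (dd > n - 2L) break
    nm <- sprintf("pcoa_d%d", dd)
    maps[[nm]] <- stage(nm, pcoa(td, dd))
    quality[[nm]] <- stage(paste0("diagnostics_", nm),
      mapping_quality(td, maps[[nm]], k = kk))
    for (mm in map_methods) {
      nm2 <- sprintf("%s_d%d", mm, dd)
      if (mm == "tsne" && dd > 3L) next
      maps[[nm2]] <- stage(nm2,
        map_space(td, mm, dd, seed = seed))
      quality[[nm2]] <- stage(paste0("diagnostics_", nm2),
        mapping_quality(td, maps[[nm2]], k = kk))
    }
  }
  report$maps <- maps
  report$quality <- quality
  report$correlation_dimension <- stage("correlation_dimension",
    correlation_dimension(td))
  if (!is.null(ranges)) {
    if (is.character(ranges)) ranges <- stage("ranges", read_ranges(ranges))
    report$mig <- stage("mig", vapply(trees, minimum_implied_gap,
                                      numeric(1L), ranges = ranges))
    best <- maps[[sprintf("pcoa_d%d", min(d_max, n - 2L))]]
    if (!is.null(best) && n > d_max + 1L)
      report$mig_axis_r2 <- stage("mig_axis_r2",
        axis_covariate_r2(best, report$mig))
  }
  if (!is.null(out_dir)) stage("write", .write_report(report, out_dir))
  report
}

#' @export
print.treespace_report <- function(x, ...) {
  cat("Tree space analysis (", x$metric, " distance, ", x$n_trees,
      " trees)\n", sep = "")
  cl <- x$clustering
  if (!is.null(cl)) {
    cat("  best clustering: ", cl$method, ", k = ", cl$k,
        ", silhouette ", round(cl$silhouette, 3), " (", cl$category,
        ")", if (isTRUE(cl$single_cluster)) " -> report a single cluster",
        "\n", sep = "")
  }
  if (!is.null(x$correlation_dimension))
    cat("  correlation dimension: ",
        round(x$correlation_dimension$dimension, 2), "\n", sep = "")
  for (nm in names(x$quality)) {
    q <- x$quality[[nm]]
    cat(sprintf("  %-14s T*C = %.3f  r2 = %.3f  MST ext = %.2f  %s\n",
                nm, q$product, q$pearson_r2, q$mst_extension,
                if (isTRUE(q$adequate)) "adequate" else "distorted"))
  }
  if (!is.null(x$mig))
    cat("  MIG range: ", round(min(x$mig), 2), " - ",
        round(max(x$mig), 2), " My\n", sep = "")
  invisible(x)
}
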