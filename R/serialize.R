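# Plain-text artifact writers: TSV payloads with JSON metadata sidecars.

#' Write a distance matrix as TSV with a JSON sidecar
#'
#' Writes the full symmetric matrix (tree identifiers as header row and
#' column) to \code{<prefix>.tsv}, the lower triangle to
#' \code{<prefix>.lower.tsv}, and metric metadata to \code{<prefix>.json}.
#'
#' @param distmat a \code{tree_dist}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_distance_matrix <- function(distmat, prefix) {
  if (!inherits(distmat, "tree_dist")) stop("expected a 'tree_dist'")
  d <- distmat$d
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(cbind(id = rownames(d), as.data.frame(d)), tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lower <- paste0(prefix, ".lower.tsv")
  n <- nrow(d)
  rows <- vapply(seq_len(n), function(i)
    paste(c(rownames(d)[i], format(d[i, seq_len(i - 1L)], trim = TRUE)),
          collapse = "\t"), character(1L))
  writeLines(rows, lower)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(metric = distmat$metric,
                            normalized = distmat$normalized,
                            n_trees = n, n_leaves = distmat$n_leaves,
                            multiplicity = distmat$multiplicity),
                       js, auto_unbox = TRUE, null = "null")
  invisible(c(tsv, lower, js))
}

#' Write an embedding as TSV with a JSON sidecar
#'
#' @param embedding a \code{tree_map}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_embedding <- function(embedding, prefix) {
  if (!inherits(embedding, "tree_map")) stop("expected a 'tree_map'")
  tsv <- paste0(prefix, ".tsv")
  df <- cbind(id = rownames(embedding$points),
              as.data.frame(embedding$points))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(method = embedding$method,
                            ndim = embedding$ndim,
                            params = embedding$params,
                            seed = embedding$seed,
                            eigenvalues = embedding$eigenvalues,
                            stress = embedding$stress,
                            correction = embedding$correction,
                            converged = embedding$converged),
                       js, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(tsv, js))
}

#' Write a clustering as TSV with a JSON report
#'
#' @param clustering a \code{tree_clustering}.
#' @param ids item identifiers (default item_1..item_n).
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_clustering <- function(clustering, prefix, ids = NULL) {
  if (!inherits(clustering, "tree_clustering"))
    stop("expected a 'tree_clustering'")
  n <- length(clustering$labels)
  if (is.null(ids)) ids <- sprintf("item_%d", seq_len(n))
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(data.frame(id = ids, cluster = clustering$labels),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(method = clustering$method, k = clustering$k,
                            silhouette = clustering$silhouette,
                            category = clustering$category,
                            single_cluster = clustering$single_cluster,
                            seed = clustering$seed),
                       js, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(tsv, js))
}

# Artifact bundle for analyze_trees().
.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  write_distance_matrix(report$distances, p("distances_", report$metric))
  write_clustering(report$clustering, p("clustering"),
                   ids = report$distances$ids)
  for (nm in names(report$maps))
    write_embedding(report$maps[[nm]], p("map_", nm))
  qual <- lapply(report$quality, unclass)
  jsonlite::write_json(qual, p("mapping_quality.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  if (!is.null(report$mig))
    utils::write.table(data.frame(id = report$distances$ids,
                                  MIG = report$mig),
                       p("mig.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  summary_lines <- utils::capture.output(print(report))
  writeLines(summary_lines, p("summary.txt"))
  invisible(out_dir)
}
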