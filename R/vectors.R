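#' Vector representation of a cladogram
#'
#' Builds the leaf-pair vector underlying the Euclidean tree metrics, with
#' one entry per unordered leaf pair in canonical order (lexicographic by
#' sorted label pair):
#' \itemize{
#'   \item \code{"path"}: number of edges between the two leaves in the
#'     unrooted topology;
#'   \item \code{"mrca-depth"}: number of edges separating the pair's most
#'     recent common ancestor from the root (rooted trees only); this is the
#'     Kendall-Colijn vector at lambda = 0;
#'   \item \code{"split-size"}: number of leaves in the smallest nontrivial
#'     split side containing both leaves, or n when no such side exists.
#' }
#'
#' @param tree a \code{phylo} tree.
#' @param kind one of \code{"path"}, \code{"mrca-depth"}, \code{"split-size"}.
#' @return named numeric vector of length choose(n, 2).
#' @examples
#' tr <- read_trees(text = "((a,b),(c,d));")[[1]]
#' tree_vector(tr, "path")
#' tree_vector(tr, "split-size")
#' @export
tree_vector <- function(tree, kind = c("path", "mrca-depth", "split-size")) {
  kind <- match.arg(kind)
  pr <- .profile(tree)
  m <- switch(kind,
    "path" = .path_matrix(pr),
    "mrca-depth" = {
      if (!pr$rooted)
        stop("mrca-depth vectors require a rooted tree")
      .mrca_depth(pr)
    },
    "split-size" = .sv_matrix(pr))
  .pair_vector(m, pr$labels)
}

#' Total cophenetic index (TCI)
#'
#' The sum, over all unordered leaf pairs, of the edge depth of the pair's
#' most recent common ancestor.  A balance index: low values denote balanced
#' trees; the rooted caterpillar attains the maximum, choose(n, 3).
#'
#' @param tree a rooted \code{phylo} tree.
#' @return a nonnegative integer.
#' @examples
#' total_cophenetic_index(read_trees(text = "((a,b),(c,d));")[[1]])
#' @export
total_cophenetic_index <- function(tree) {
  pr <- .profile(tree)
  if (!pr$rooted) stop("the total cophenetic index requires a rooted tree")
  sum(.ut(.mrca_depth(pr)))
}
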