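#' Read cladograms from Newick or NEXUS text
#'
#' Parses one or more trees from a file or a character string.  Newick input
#' holds one ';'-terminated tree per statement; NEXUS input is recognised by
#' a leading \code{#NEXUS} and may use a TRANSLATE table.  Branch lengths and
#' support values are silently discarded: all trees are treated as
#' cladograms.  Input order is preserved.
#'
#' @param file path to a tree file, or \code{NULL} if \code{text} is given.
#' @param text character scalar holding Newick or NEXUS text.
#' @return an object of class \code{multiPhylo} (a list of \code{phylo}
#'   trees without edge lengths).
#' @examples
#' trees <- read_trees(text = "((a,b),(c,d));\n((a,c),(b,d));")
#' length(trees)
#' @export
read_trees <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    trees <- tryCatch(ape::read.nexus(tf),
                      error = function(e) stop("NEXUS parse error: ",
                                               conditionMessage(e)))
    if (inherits(trees, "phylo")) trees <- c(trees)
  } else {
    stmts <- strsplit(text, ";", fixed = TRUE)[[1L]]
    stmts <- stmts[grepl("\\S", stmts)]
    if (!length(stmts)) stop("no trees found in input")
    trees <- vector("list", length(stmts))
    for (i in seq_along(stmts)) {
      s <- stmts[i]
      if (.paren_unbalanced(s))
        stop("tree ", i, ": malformed parenthesis structure")
      trees[[i]] <- tryCatch(
        ape::read.tree(text = paste0(s, ";")),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(trees[[i]]))
        stop("tree ", i, ": parse error")
    }
    class(trees) <- "multiPhylo"
  }
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    tr$edge.length <- NULL
    tr$node.label <- NULL
    if (anyDuplicated(tr$tip.label))
      stop("tree ", i, ": duplicate label \"",
           tr$tip.label[duplicated(tr$tip.label)][1L], "\"")
    trees[[i]] <- tr
  }
  trees
}

.paren_unbalanced <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  bal <- cumsum((ch == "(") - (ch == ")"))
  any(bal < 0L) || bal[length(bal)] != 0L
}

#' Write cladograms as Newick text
#'
#' @param trees a \code{phylo} or \code{multiPhylo} object.
#' @param file output path, or \code{NULL} to return the text.
#' @return the Newick text, invisibly when written to a file.
#' @export
write_trees <- function(trees, file = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  txt <- vapply(trees, function(tr) {
    tr$edge.length <- NULL
    ape::write.tree(tr)
  }, character(1L))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Extract the nontrivial splits (bipartitions) of a tree
#'
#' A split is the unordered bipartition of the leaf set induced by an
#' internal edge of the unrooted topology; it is nontrivial when both sides
#' contain at least two leaves.  Root placement does not affect the result.
#'
#' @param tree a \code{phylo} tree.
#' @return a list of splits; each element is a list with components
#'   \code{A} and \code{B} (character vectors of leaf labels, \code{A} the
#'   side not containing the alphabetically first label).
#' @examples
#' tree_splits(read_trees(text = "((a,b),(c,d));")[[1]])
#' @export
tree_splits <- function(tree) {
  pr <- .profile(tree)
  S <- .splits_logical(pr)
  lapply(seq_len(nrow(S)), function(i) {
    list(A = pr$labels[S[i, ]], B = pr$labels[!S[i, ]])
  })
}

#' Subsample an ordered tree list as a posterior sample
#'
#' Deterministically drops an initial burn-in fraction, then takes
#' \code{target_count} trees at uniform intervals across the remainder.
#' If fewer trees remain than requested, all of them are kept.
#'
#' @param trees a \code{multiPhylo} or list of trees (or any vector/list).
#' @param burnin_fraction fraction in [0, 1) to discard from the start.
#' @param target_count number of trees to retain.
#' @return the subsampled list, input order preserved.
#' @examples
#' subsample_posterior(as.list(1:10), 0.5, 3)
#' @export
subsample_posterior <- function(trees, burnin_fraction = 0.5,
                                target_count = 2500L) {
  n <- length(trees)
  if (n == 0L) stop("empty tree list")
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("burnin_fraction must be in [0, 1)")
  if (target_count < 1L) stop("target_count must be >= 1")
  drop <- floor(burnin_fraction * n)
  kept <- seq.int(drop + 1L, n)
  m <- length(kept)
  if (m > target_count) {
    idx <- round(seq(1L, m, length.out = target_count))
    kept <- kept[idx]
  }
  trees[kept]
}
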