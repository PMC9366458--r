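# Stratigraphic congruence: minimum implied gap and a synthetic
# stratigraphy generator.  Dates are Ma before present (larger = older).

#' Read stratigraphic ranges from a TSV file
#'
#' Columns: \code{taxon}, \code{FAD} (first appearance, Ma) and optionally
#' \code{LAD} (last appearance, Ma, with FAD >= LAD >= 0).
#'
#' @param file path to the tab-separated table.
#' @return data frame with columns \code{taxon}, \code{FAD} and
#'   (if present) \code{LAD}.
#' @export
read_ranges <- function(file) {
  rg <- utils::read.delim(file, stringsAsFactors = FALSE)
  names(rg) <- sub("^fad$", "FAD", sub("^lad$", "LAD", tolower(names(rg))))
  if (!all(c("taxon", "FAD") %in% names(rg)))
    stop("range table needs 'taxon' and 'FAD' columns")
  .validate_ranges(rg)
  rg
}

.validate_ranges <- function(rg) {
  if (any(!is.finite(rg$FAD)) || any(rg$FAD < 0))
    stop("FAD values must be finite and >= 0")
  if (!is.null(rg$LAD)) {
    ok <- is.finite(rg$LAD) & rg$LAD >= 0 & rg$FAD >= rg$LAD
    if (any(!ok))
      stop("LAD values must satisfy FAD >= LAD >= 0 (offending taxa: ",
           paste(rg$taxon[!ok], collapse = ", "), ")")
  }
  invisible(rg)
}

#' Minimum implied gap (MIG)
#'
#' Sum, over all edges of a rooted cladogram, of the fossil-record gap each
#' edge implies when every internal node is dated at the oldest first
#' appearance among its leaf descendants -- the dating that minimises total
#' gap.  Only FADs enter the statistic; a small MIG denotes good agreement
#' between tree and stratigraphy.  The edge subtending the root contributes
#' no gap (no origin time before the root is assumed).
#'
#' @param tree a rooted \code{phylo} tree.
#' @param ranges data frame with \code{taxon} and \code{FAD} (Ma), or a
#'   named numeric vector of FADs.
#' @return nonnegative real (million years).
#' @examples
#' tr <- read_trees(text = "((A,B),C);")[[1]]
#' minimum_implied_gap(tr, c(A = 10, B = 20, C = 30))  # 20
#' @export
minimum_implied_gap <- function(tree, ranges) {
  pr <- .profile(tree)
  if (!pr$rooted) stop("MIG requires a rooted tree")
  fad <- .fad_vector(ranges, tree$tip.label)
  nn <- pr$nn
  date <- numeric(nn)
  date[seq_len(pr$n)] <- fad
  # node date = oldest descendant FAD (canonical columns -> FAD by rank)
  fad_canon <- numeric(pr$n)
  fad_canon[pr$rank] <- fad
  for (v in pr$internal) date[v] <- max(fad_canon[pr$M[v, ]])
  child <- which(pr$parent > 0L)
  sum(date[pr$parent[child]] - date[child])
}

.fad_vector <- function(ranges, tip_labels) {
  if (is.data.frame(ranges)) {
    .validate_ranges(ranges)
    fad <- stats::setNames(ranges$FAD, ranges$taxon)
  } else {
    fad <- ranges
  }
  missing <- setdiff(tip_labels, names(fad))
  if (length(missing))
    stop("no FAD for taxa: ", paste(missing, collapse = ", "))
  out <- fad[tip_labels]
  if (any(!is.finite(out)) || any(out < 0))
    stop("FAD values must be finite and >= 0")
  unname(out)
}

#' Simulate stratigraphic ranges congruent with a reference tree
#'
#' Assigns each leaf a first-appearance date from the reference topology:
#' internal nodes are placed at \code{depth_scale} million years per edge
#' below the root, each leaf's lineage originates at its parent's time, and
#' an absolute truncated-Gaussian error of scale \code{noise} (My) makes the
#' record incomplete by pulling first appearances towards the present
#' (never below 0 Ma).  The resulting FADs track the reference's node
#' order, so the reference attains a near-minimal MIG and trees further
#' from it (e.g. by NNI moves) tend to imply larger gaps.
#'
#' @param reference a rooted \code{phylo} tree.
#' @param depth_scale million years per edge (> 0).
#' @param noise truncated-Gaussian scale in My (>= 0).
#' @return data frame with columns \code{taxon} and \code{FAD}.
#' @examples
#' set.seed(1)
#' tr <- random_tree(8, rooted = TRUE)
#' simulate_stratigraphy(tr, depth_scale = 5, noise = 1)
#' @export
simulate_stratigraphy <- function(reference, depth_scale = 5, noise = 0) {
  pr <- .profile(reference)
  if (!pr$rooted) stop("the reference tree must be rooted")
  if (depth_scale <= 0) stop("depth_scale must be > 0")
  if (noise < 0) stop("noise must be >= 0")
  height <- max(pr$depth) * depth_scale
  origin <- height - pr$depth[pr$parent[seq_len(pr$n)]] * depth_scale
  eps <- if (noise > 0) abs(stats::rnorm(pr$n, 0, noise)) else 0
  fad <- pmax(0, origin - eps)
  data.frame(taxon = reference$tip.label, FAD = fad,
             stringsAsFactors = FALSE)
}
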