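#' Read a Newick tree
#'
#' Parses a rooted Newick string or file into an [ape::read.tree()] `phylo`
#' object, enforcing the conventions the rest of the package assumes: branch
#' lengths present on all edges and non-negative, and unique tip labels.
#' Internal node labels are tolerated and preserved; polytomies are allowed.
#'
#' @param text Newick string (exactly one of `text`/`file`).
#' @param file Path to a Newick file.
#' @return A `phylo` object.
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text)
    else ape::read.tree(file = file),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: parser returned no tree")
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tr$edge.length))
    stop("branch lengths are required on all edges")
  if (anyNA(tr$edge.length))
    stop("branch lengths are required on all edges (found an edge without one)")
  if (any(tr$edge.length < 0))
    stop("negative branch length")
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
writeNewick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Root-to-tip depths
#'
#' @param tree A `phylo` object.
#' @return Named vector of root-to-tip path lengths (Myr).
#' @export
tipDepths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Ultrametricity check (advisory)
#'
#' Empirical time-calibrated trees are numerically imperfect, so
#' ultrametricity is checked to a relative tolerance and reported as a flag
#' rather than enforced.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on the spread of root-to-tip depths.
#' @return Logical.
#' @export
isUltrametric <- function(tree, tol = 1e-6) {
  d <- tipDepths(tree)
  (max(d) - min(d)) <= tol * max(d)
}

#' Drop tips from a tree
#'
#' Removes the named tips; resulting degree-2 nodes are suppressed with their
#' branch lengths summed, so root-to-tip depths and pairwise MRCA depths of
#' retained tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param drop Character vector of tip labels to remove (may be empty).
#' @return The pruned `phylo` object.
#' @export
pruneTips <- function(tree, drop) {
  stopifnot(inherits(tree, "phylo"))
  drop <- as.character(drop)
  if (length(drop) == 0) return(tree)
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(tree$tip.label) - length(drop) < 2)
    stop("fewer than 2 tips would remain")
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the root-to-MRCA path length shared by tips i and j; the
#' diagonal holds root-to-tip depths. Rows and columns follow the canonical
#' order (sorted tip labels) so outputs are bit-stable across topologically
#' identical inputs.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return A symmetric positive semi-definite matrix with dimnames.
#' @export
phyloVcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv(tree)
  ord <- order(rownames(C))
  C[ord, ord, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` returns the matrix as-is, `lambda = 0` the
#' star-phylogeny (diagonal) structure.
#'
#' @param C Phylogenetic covariance matrix (as from [phyloVcv()]).
#' @param lambda Scalar in \[0, 1\]; values above 1 up to the matrix-feasible
#'   maximum are allowed only with `unbounded = TRUE`.
#' @param unbounded Allow `lambda > 1` if the result stays positive definite.
#' @return The transformed matrix.
#' @export
lambdaTransform <- function(C, lambda, unbounded = FALSE) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("lambda must be a single value >= 0")
  if (!unbounded && lambda > 1)
    stop("lambda must lie in [0, 1] (set unbounded = TRUE to relax)")
  out <- C * lambda
  diag(out) <- diag(C)
  if (unbounded && lambda > 1) {
    ok <- tryCatch({ chol(out); TRUE }, error = function(e) FALSE)
    if (!ok) stop("lambda exceeds the matrix-feasible maximum")
  }
  out
}
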