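#' Read and validate a phylogenetic tree in newick format
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that enforces the
#' invariants the clustering stages rely on: unique non-empty leaf labels,
#' at least two leaves, and a finite non-negative branch length on every
#' edge. Consensus trees with multifurcations are accepted.
#'
#' @param path path to a file containing one newick string, or a newick
#'   string passed via \code{text}.
#' @param text optional newick string (bypasses \code{path}).
#' @return an \code{\link[ape]{ape}} \code{phylo} object.
#' @export
readNewickTree <- function(path, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("newick parse error: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(tr))
    stop("newick parse error: no tree could be read", call. = FALSE)
  validatePhyloTree(tr)
  tr
}

validatePhyloTree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object", call. = FALSE)
  if (length(tr$tip.label) < 2L)
    stop("tree must have at least 2 leaves", call. = FALSE)
  if (any(!nzchar(tr$tip.label)))
    stop("leaf labels must be non-empty", call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  bad <- !is.finite(tr$edge.length) | tr$edge.length < 0
  if (any(bad))
    stop(sum(bad), " branch length(s) missing, non-finite or negative",
         call. = FALSE)
  invisible(tr)
}

#' Patristic distance matrix of a tree
#'
#' Pairwise evolutionary distances between leaves: the sum of branch
#' lengths (expected substitutions per site) along the unique path joining
#' each leaf pair. The result is independent of root placement.
#'
#' @param tree a \code{phylo} object (see \code{\link{readNewickTree}}).
#' @return a labelled symmetric numeric matrix with zero diagonal, leaf
#'   labels in tree order.
#' @export
patristicDistances <- function(tree) {
  validatePhyloTree(tree)
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label, drop = FALSE]
  validateDistanceMatrix(d)
  d
}

#' Validate a distance matrix
#'
#' Checks symmetry, zero diagonal, non-negativity, finiteness and label
#' consistency for a patristic (or other) distance matrix.
#'
#' @param d a square numeric matrix with identical row/column names.
#' @param tol symmetry tolerance.
#' @return the matrix, invisibly; errors otherwise.
#' @export
validateDistanceMatrix <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || !is.numeric(d)) stop("distance matrix must be numeric")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop("distance matrix must carry row and column labels")
  if (!identical(rownames(d), colnames(d)))
    stop("row and column labels differ")
  if (anyDuplicated(rownames(d))) stop("duplicate labels")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(d)) > tol)) stop("diagonal must be zero")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  invisible(d)
}

#' Write a distance matrix as tab-separated square text
#'
#' Square layout with a header row and a leading label column; values are
#' printed with 15 significant digits so cutoff comparisons survive a
#' round-trip unchanged.
#'
#' @param d labelled distance matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  validateDistanceMatrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("label", colnames(d)), collapse = "\t"), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], sprintf("%.15g", d[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a square tab-separated distance matrix
#'
#' @param path file written by \code{\link{writeDistanceMatrix}} (or any
#'   square TSV with a label header row and label first column).
#' @return labelled symmetric numeric matrix.
#' @export
readDistanceMatrix <- function(path) {
  x <- utils::read.delim(path, header = TRUE, row.names = 1,
                         check.names = FALSE, comment.char = "#")
  d <- as.matrix(x)
  storage.mode(d) <- "double"
  colnames(d) <- colnames(x)
  validateDistanceMatrix(d)
  d
}
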