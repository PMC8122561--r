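# ---------------------------------------------------------------------------
# Sanity-check phylogenetic plumbing: p-distance matrix and a
# neighbour-joining tree (via ape) so locus outputs can be smoke-tested
# end-to-end.  Likelihood/Bayesian inference is deliberately out of scope.
# ---------------------------------------------------------------------------

#' Uncorrected p-distance matrix of an alignment
#'
#' Complete deletion: columns containing any gap or ambiguity code are
#' removed, then `d_ij = differing columns / retained columns`.
#'
#' @param aln A [locus_alignment()] with `n >= 2` rows.
#' @return Symmetric numeric matrix with zero diagonal, dimnames set to the
#'   accessions.  Zero retained columns is an error.
#' @export
p_distance_matrix <- function(aln) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("p_distance_matrix: need at least 2 sequences")
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  keep <- colSums(ok) == n
  if (!any(keep)) stop("p_distance_matrix: zero retained columns")
  m2 <- m[, keep, drop = FALSE]
  L <- ncol(m2)
  d <- matrix(0, n, n, dimnames = list(names(aln$rows), names(aln$rows)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- sum(m2[i, ] != m2[j, ]) / L
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via \pkg{ape}), with labels sorted before
#' joining so that ties are broken deterministically by label order, and
#' negative branch lengths clamped at zero.
#'
#' @param d Symmetric distance matrix with labels as dimnames (`n >= 3`).
#' @param path Optional file; when given the tree is also written there in
#'   Newick format.
#' @return The Newick string (class `character`); the `phylo` object is
#'   attached as attribute `tree`.
#' @export
nj_tree <- function(d, path = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("nj_tree: d must be a square matrix")
  if (nrow(d) < 3L) stop("nj_tree: need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("nj_tree: d must be symmetric")
  o <- order(rownames(d))
  d <- d[o, o]
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  newick <- ape::write.tree(tr)
  if (!is.null(path)) writeLines(newick, path)
  attr(newick, "tree") <- tr
  newick
}

#' Write a distance matrix as a PHYLIP-style TSV
#'
#' @param d Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(label = rownames(d), round(d, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
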