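# Distance matrices, neighbor-joining trees with clamped branch
# lengths, column-resampling bootstrap supports, and newick I/O.
# Tree algorithms are delegated to ape.

#' Pairwise identity distance matrix
#'
#' \eqn{d(i,j) = 1 - } identity\eqn{(i,j)} from pairwise global
#' alignment, with identity = matches / alignment length including gap
#' columns (configurable to matches / shorter sequence length).
#' Symmetric with zero diagonal.
#'
#' @param seqs named [Biostrings::DNAStringSet] or character vector of
#'   >= 2 sequences with unique labels.
#' @param denominator identity denominator, \code{"alignment"}
#'   (default) or \code{"shorter"}.
#' @return symmetric numeric matrix with sequence labels.
#' @export
distanceMatrix <- function(seqs, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  seqs <- setNames(as.character(seqs), names(seqs))
  if (length(seqs) < 2L) stop("distanceMatrix(): need >= 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("distanceMatrix(): duplicate or missing labels")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        1 - alnIdentity(seqs[[i]], seqs[[j]], denominator = denominator)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (exact on additive matrices), with
#' negative branch lengths clamped to zero and the deficit moved to the
#' sibling edge so path lengths are preserved as far as possible. A
#' 2-taxon input yields the single-edge tree whose total length is the
#' input distance.
#'
#' @param d symmetric distance matrix (or "dist") with labels.
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
  if (methods::is(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("njTree(): distance matrix must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- colnames(d)
  if (is.null(labs)) {
    labs <- paste0("t", seq_len(nrow(d)))
    dimnames(d) <- list(labs, labs)
  }
  n <- nrow(d)
  if (n < 2L) stop("njTree(): need >= 2 taxa")
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = labs, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  clampNegativeBranches(ape::nj(stats::as.dist(d)))
}

# set negative branch lengths to 0, adding the deficit to a sibling
# edge (another edge sharing the same parent node)
clampNegativeBranches <- function(tree) {
  el <- tree$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sibs)) el[sibs[1L]] <- el[sibs[1L]] + el[e]
    el[e] <- 0
  }
  tree$edge.length <- el
  tree
}

# p-distance matrix from an alignment matrix (rows = taxa, columns =
# sites): mismatch fraction over columns where both rows are ungapped
# (pairwise deletion); 1 when no shared column exists
alignmentDistance <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- aln[i, ] != "-" & aln[j, ] != "-"
      d[i, j] <- d[j, i] <-
        if (!any(ok)) 1 else mean(aln[i, ok] != aln[j, ok])
    }
  }
  d
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the base tree from a fixed multiple alignment
#' ([starAlignment()] when raw sequences are given), then resamples
#' alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition the fraction of
#' replicates containing it (in [0, 1], stored as node labels).
#' Seeded and deterministic.
#'
#' @param x a character alignment matrix (rows = taxa) or >= 3 named
#'   sequences.
#' @param nBoot number of bootstrap replicates (>= 1).
#' @param seed integer seed (optional).
#' @return an [ape::phylo] tree with \code{node.label} supports.
#' @export
bootstrapSupport <- function(x, nBoot = 100, seed = NULL) {
  stopifnot(nBoot >= 1)
  aln <- if (is.matrix(x)) x else starAlignment(x)
  if (ncol(aln) < 2L) stop("bootstrapSupport(): alignment shorter than 2 columns")
  if (nrow(aln) < 3L) stop("bootstrapSupport(): need >= 3 taxa")
  tree <- njTree(alignmentDistance(aln))
  counts <- withSeed(seed,
    ape::boot.phylo(tree, aln,
                    FUN = function(m) njTree(alignmentDistance(m)),
                    B = nBoot, quiet = TRUE))
  counts[is.na(counts)] <- nBoot   # the root split is trivially present
  tree$node.label <- counts / nBoot
  tree
}

#' Read / write newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()];
#' bootstrap supports ride as internal node labels in [0, 1] and
#' round-trip.
#'
#' @param path file path.
#' @return `readNewick()`: an [ape::phylo]; node labels parsed to
#'   numeric when they are numbers.
#' @export
readNewick <- function(path) {
  tree <- ape::read.tree(path)
  if (!is.null(tree$node.label)) {
    num <- suppressWarnings(as.numeric(tree$node.label))
    if (!all(is.na(num) & nzchar(tree$node.label))) tree$node.label <- num
  }
  tree
}

#' @param tree an [ape::phylo].
#' @rdname readNewick
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
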