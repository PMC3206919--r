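## PH85 (Penny & Hendy) topology distance and the gene-tree NJ dendrogram.

## Canonical non-trivial bipartitions of a tree as strings. Each split is
## represented by the side not containing the alphabetically first label,
## sorted and joined with "|". Polytomies simply contribute fewer splits.
nontrivialSplits <- function(tree) {
  labs <- tree$tip.label
  all_sorted <- sort(labs)
  ref <- all_sorted[1L]
  n <- length(labs)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(all_sorted, side)
    k <- length(side)
    if (k >= 2L && k <= n - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' PH85 topology distance
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets — twice the number of conflicting splits when both
#' trees are binary. Zero iff the unrooted topologies agree.
#'
#' @param t1,t2 `phylo` trees over identical leaf sets.
#' @return nonnegative integer.
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' ph85(t1, t2)  # 2
#' @export
ph85 <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("comparison error: leaf sets differ")
  s1 <- nontrivialSplits(t1)
  s2 <- nontrivialSplits(t2)
  sum(!(s1 %in% s2)) + sum(!(s2 %in% s1))
}

#' Pairwise PH85 distance matrix
#'
#' @param trees named list of `phylo` trees over a shared taxon set.
#' @return symmetric integer matrix with the tree names as dimnames.
#' @export
ph85Matrix <- function(trees) {
  if (is.null(names(trees)))
    names(trees) <- paste0("tree", seq_along(trees))
  n <- length(trees)
  splits <- lapply(trees, nontrivialSplits)
  d <- matrix(0L, n, n, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s1 <- splits[[i]]; s2 <- splits[[j]]
    d[i, j] <- d[j, i] <- sum(!(s1 %in% s2)) + sum(!(s2 %in% s1))
  }
  d
}

#' NJ dendrogram of gene-tree distances
#'
#' Builds the Neighbor-Joining dendrogram of the PH85 distances between
#' the supplied (gene or partition) trees; leaf labels are the tree names.
#' Groups genes by the similarity of their topologies.
#'
#' @param trees named list of at least 3 `phylo` trees, shared taxon set.
#' @return an unrooted `phylo` with one leaf per input tree.
#' @export
treeDistanceDendrogram <- function(trees) {
  if (length(trees) < 3L) stop("need at least 3 trees")
  njTree(ph85Matrix(trees))
}
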