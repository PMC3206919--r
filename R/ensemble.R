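## Posterior tree-ensemble handling: IO, burn-in, clade posterior
## probabilities, credible sets.

#' Read a posterior tree sample
#'
#' Reads an ordered tree sample from a file of newick strings (one per
#' line) or a NEXUS trees block (translate tables resolved), preserving
#' file order for burn-in semantics.
#'
#' @param path file path.
#' @param format "newick" or "nexus".
#' @return a [TreeEnsemble-class] (no per-sample scalars).
#' @export
readTrees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trs <- if (format == "newick") ape::read.tree(path)
         else ape::read.nexus(path)
  if (inherits(trs, "phylo")) trs <- list(trs)
  else if (!is.null(attr(trs, "TipLabel")))
    trs <- ape::.uncompressTipLabel(trs)
  treeEnsemble(trs)
}

#' Write a tree ensemble as newick, one tree per line
#'
#' @param e a [TreeEnsemble-class] or list of `phylo`.
#' @param path output file.
#' @export
writeTrees <- function(e, path) {
  trs <- if (is(e, "TreeEnsemble")) ensembleTrees(e) else e
  class(trs) <- "multiPhylo"
  ape::write.tree(trs, file = path)
  invisible(path)
}

#' Discard burn-in samples
#'
#' Removes the first `floor(fraction * n)` samples of the ensemble
#' (default 10%).
#'
#' @param e a [TreeEnsemble-class].
#' @param fraction burn-in fraction in \[0, 1).
#' @return the truncated [TreeEnsemble-class].
#' @export
applyBurnin <- function(e, fraction = 0.1) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- nSamples(e)
  drop <- floor(fraction * n)
  if (drop >= n) stop("burn-in error: no samples left")
  keep <- (drop + 1L):n
  st <- ensembleStats(e)
  treeEnsemble(ensembleTrees(e)[keep],
               if (ncol(st) > 0L) st[keep, , drop = FALSE] else st)
}

## Is `taxa` a monophyletic group on this rooted tree?
isCladeIn <- function(tree, taxa) {
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) stop("clade taxa not all present in tree")
  if (length(idx) < 2L) stop("clade must have at least 2 taxa")
  if (length(idx) == length(tree$tip.label)) return(TRUE)
  mrca <- ape::getMRCA(tree, idx)
  tips <- phangorn::Descendants(tree, mrca, type = "tips")[[1L]]
  length(tips) == length(idx)
}

#' Clade posterior probability
#'
#' Fraction of ensemble samples in which the query taxa form a rooted
#' monophyletic group. Apply burn-in first ([applyBurnin()]); support
#' calls in this analysis treat PP > 0.6 as the minimum threshold for
#' monophyly.
#'
#' @param e a [TreeEnsemble-class] (post burn-in).
#' @param taxa character vector of at least two tip labels.
#' @return probability in \[0, 1\].
#' @export
cladePP <- function(e, taxa) {
  mean(vapply(ensembleTrees(e), isCladeIn, TRUE, taxa = taxa))
}

#' 95% credible set of trees
#'
#' Subsets the ensemble to samples whose posterior log density lies inside
#' the highest-posterior-density interval of that scalar at the given
#' level (the per-sample `posterior` column of the ensemble stats).
#'
#' @param e a [TreeEnsemble-class] with a `posterior` stats column.
#' @param level credibility level (default 0.95).
#' @return the retained [TreeEnsemble-class].
#' @export
credibleSet <- function(e, level = 0.95) {
  st <- ensembleStats(e)
  if (!"posterior" %in% colnames(st))
    stop("credible-set error: per-sample posterior densities missing")
  x <- st$posterior
  if (level >= 1) return(e)
  iv <- hpdInterval(x, level)
  keep <- which(x >= iv[1L] & x <= iv[2L])
  treeEnsemble(ensembleTrees(e)[keep], st[keep, , drop = FALSE])
}

#' Is a topology contained in a tree set?
#'
#' TRUE iff some sample of the set has PH85 distance zero to the query
#' tree, i.e. the query topology occurs in (for instance) the 95% credible
#' set of a gene's posterior.
#'
#' @param cs a [TreeEnsemble-class] (e.g. from [credibleSet()]).
#' @param tree a `phylo` with the same taxon set.
#' @return logical.
#' @export
containsTopology <- function(cs, tree) {
  for (s in ensembleTrees(cs)) if (ph85(s, tree) == 0L) return(TRUE)
  FALSE
}
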