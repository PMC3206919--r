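## Maximum-clade-credibility tree with common-ancestor median heights.

## Heights (age before present) of every node of an ultrametric tree.
nodeAges <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

## Clades of a rooted tree: canonical label-set key and node id per
## internal node (including the root).
cladeKeys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- tree$tip.label
  nodes <- seq_len(tree$Nnode) + length(labs)
  keys <- vapply(pp, function(cl) paste(sort(labs[cl]), collapse = "|"), "")
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

#' Maximum-clade-credibility tree
#'
#' Returns the sampled tree maximizing the product of clade posterior
#' frequencies over its clades (ties broken by earliest sample index).
#' Node heights of the returned tree are re-annotated with the per-clade
#' median height across all samples containing that clade
#' (common-ancestor heights); a root-to-tip pass clamps any non-monotone
#' medians so child heights never exceed their parent's.
#'
#' @param e a [TreeEnsemble-class] (post burn-in).
#' @return a `phylo`; the clade-credibility score is attached as
#'   attribute `"logCladeCredibility"`.
#' @export
mccTree <- function(e) {
  trs <- ensembleTrees(e)
  n <- length(trs)
  keyed <- lapply(trs, cladeKeys)
  counts <- table(unlist(lapply(keyed, function(k) unique(k$key))))
  freq <- as.numeric(counts) / n
  names(freq) <- names(counts)
  score <- vapply(seq_len(n), function(i)
    sum(log(freq[keyed[[i]]$key])), 0)
  best <- which.max(score)  # earliest index on ties
  tree <- trs[[best]]

  ## median height per clade across samples containing it
  hts <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    ages <- nodeAges(trs[[i]])
    k <- keyed[[i]]
    for (j in seq_len(nrow(k))) {
      key <- k$key[j]
      hts[[key]] <- c(hts[[key]], ages[k$node[j]])
    }
  }
  k <- keyed[[best]]
  ntip <- length(tree$tip.label)
  h <- numeric(ntip + tree$Nnode)  # tips at height 0
  for (j in seq_len(nrow(k)))
    h[k$node[j]] <- median(hts[[k$key[j]]])
  ## clamp: preorder so each child sits below its parent
  ord <- rev(ape::postorder(tree))
  for (ei in ord) {
    par <- tree$edge[ei, 1L]; chl <- tree$edge[ei, 2L]
    if (chl > ntip && h[chl] > h[par]) h[chl] <- h[par]
  }
  tree$edge.length <- h[tree$edge[, 1L]] - h[tree$edge[, 2L]]
  attr(tree, "logCladeCredibility") <- score[best]
  tree
}
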