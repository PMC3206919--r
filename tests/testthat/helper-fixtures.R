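## Shared fixtures, built in code.

## Small aligned FASTA written to a temp file.
writeFastaFixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

## NEXUS character matrix equivalent to the same sequences.
writeNexusFixture <- function(seqs, path = tempfile(fileext = ".nex")) {
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs),
                     nchar(seqs[[1L]])),
             "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX",
             vapply(names(seqs), function(nm)
               paste(nm, seqs[[nm]]), ""),
             ";", "END;")
  writeLines(lines, path)
  path
}

## NEXUS trees block with a translate table.
writeNexusTreesFixture <- function(newicks, labels,
                                   path = tempfile(fileext = ".nex")) {
  tr <- paste(sprintf("    %d %s%s", seq_along(labels), labels,
                      c(rep(",", length(labels) - 1L), ";")),
              collapse = "\n")
  body <- vapply(seq_along(newicks), function(i)
    sprintf("tree STATE_%d = %s", i, newicks[[i]]), "")
  writeLines(c("#NEXUS", "Begin trees;", "  Translate", tr, body, "End;"),
             path)
  path
}

## Deterministic ensemble with a clade planted in a given fraction of
## samples: ((A,B),C),(D,E) vs ((A,C),B),(D,E) style 5-taxon trees.
plantedEnsemble <- function(n_with, n_without) {
  t_with <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:2,E:2):1);")
  t_without <- ape::read.tree(text = "(((A:1,C:1):1,B:2):1,(D:2,E:2):1);")
  treeEnsemble(c(rep(list(t_with), n_with),
                 rep(list(t_without), n_without)))
}

## Random binary tree over n taxa (topology only), labels A, B, ...
randomTopology <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- LETTERS[seq_len(n)]
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

## Brute-force non-trivial bipartitions of a tree (independent of the
## package's split extraction): for every internal edge, the tip set
## below it, canonicalized on the side without the first sorted label.
bruteSplits <- function(tree) {
  labs <- sort(tree$tip.label)
  ref <- labs[1L]
  n <- length(labs)
  ntip <- length(tree$tip.label)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, below))
  }
  keys <- character(0)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    side <- below(node)
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= n - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

supportFixturePath <- function()
  system.file("extdata", "orcinus_clade_support.csv",
              package = "mitopart")

tmrcaFixturePath <- function()
  system.file("extdata", "tmrca_medians.csv", package = "mitopart")
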