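## Codon and gene partition schemes over a (possibly concatenated)
## alignment, plus RAxML-style partition-file export.

codonPositionOf <- function(i, frame) ((i - 1L - frame) %% 3L) + 1L

#' Build a partitioning scheme from gene annotations
#'
#' Assigns the sites of annotated genes to blocks. `by_codon` pools codon
#' positions 1/2/3 across genes (positions assigned from each gene's
#' reading-frame offset), `by_gene` makes one block per gene,
#' `by_gene_and_codon` makes three blocks per gene, and `unpartitioned`
#' lumps all annotated sites in one block. Overlap-duplicated sites are
#' counted once per gene containing them.
#'
#' @param aln a [MitoAlignment-class] the coordinates refer to.
#' @param genes annotation data.frame (rows as from [geneAnnotation()]).
#' @param mode one of "by_codon", "by_gene", "by_gene_and_codon",
#'   "unpartitioned".
#' @return a [PartitionScheme-class].
#' @export
codonPartition <- function(aln, genes,
                           mode = c("by_gene_and_codon", "by_codon",
                                    "by_gene", "unpartitioned")) {
  mode <- match.arg(mode)
  n <- nSites(aln)
  codonMode <- mode %in% c("by_codon", "by_gene_and_codon")
  if (codonMode && !all(genes$coding))
    stop("partition error: non-coding gene '",
         genes$name[!genes$coding][1L], "' under a codon mode")
  perGene <- lapply(seq_len(nrow(genes)), function(i) {
    g <- as.list(genes[i, ])
    sites <- geneSites(g, n)
    if (g$strand == "-") sites <- rev(sites)  # 5'->3' order for codons
    list(name = g$name, sites = sites,
         pos = codonPositionOf(seq_along(sites), g$frame))
  })
  blocks <- switch(mode,
    unpartitioned = list(all = unlist(lapply(perGene, `[[`, "sites"))),
    by_gene = setNames(lapply(perGene, `[[`, "sites"),
                       vapply(perGene, `[[`, "", "name")),
    by_codon = {
      b <- lapply(1:3, function(p)
        unlist(lapply(perGene, function(g) g$sites[g$pos == p])))
      setNames(b, paste0("pos", 1:3))
    },
    by_gene_and_codon = {
      out <- list()
      for (g in perGene)
        for (p in 1:3)
          out[[paste0(g$name, "_pos", p)]] <- g$sites[g$pos == p]
      out
    })
  blocks <- blocks[lengths(blocks) > 0L]
  ## duplicates within a block can only come from the same site annotated
  ## in two pooled genes (by_codon / unpartitioned): keep one copy there
  if (mode %in% c("by_codon", "unpartitioned"))
    blocks <- lapply(blocks, unique)
  partitionScheme(mode, blocks)
}

## Compress an integer set into "a-b" / "a-b\3" range strings.
compressSites <- function(sites) {
  s <- sites
  out <- character(0)
  while (length(s)) {
    if (length(s) >= 3L && all(diff(s) == 3L)) {
      out <- c(out, sprintf("%d-%d\\3", s[1L], s[length(s)]))
      s <- integer(0)
    } else {
      run <- 1L
      while (run < length(s) && s[run + 1L] == s[run] + 1L) run <- run + 1L
      out <- c(out, if (run == 1L) sprintf("%d", s[1L])
               else sprintf("%d-%d", s[1L], s[run]))
      s <- s[-seq_len(run)]
    }
  }
  paste(out, collapse = ", ")
}

#' Write a partition scheme as a RAxML-style partition file
#'
#' One line per block: `DNA, name = ranges`, with stride-3 codon ranges
#' written in `start-end\3` syntax.
#'
#' @param scheme a [PartitionScheme-class].
#' @param path output file.
#' @export
writePartitionScheme <- function(scheme, path) {
  lines <- vapply(names(blocks(scheme)), function(nm)
    sprintf("DNA, %s = %s", nm, compressSites(sort(blocks(scheme)[[nm]]))),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Slice an alignment to one block of a scheme
#'
#' @param aln a [MitoAlignment-class].
#' @param scheme a [PartitionScheme-class].
#' @param block block name or index.
#' @return a [MitoAlignment-class] of the block's columns.
#' @export
extractBlock <- function(aln, scheme, block) {
  sites <- blocks(scheme)[[block]]
  if (is.null(sites)) stop("no block '", block, "' in scheme")
  m <- as.matrix(aln)[, sites, drop = FALSE]
  colnames(m) <- NULL
  new("MitoAlignment", seqs = m)
}
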