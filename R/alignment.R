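## Alignment IO and gene extraction.
## Coordinates are 1-based inclusive; a gene with end < start wraps the
## circular origin (GenBank mtDNA convention).

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
                      R = "Y", Y = "R", K = "M", M = "K", S = "S", W = "W",
                      B = "V", V = "B", D = "H", H = "D", N = "N",
                      "-" = "-", "?" = "?")

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA file (via Biostrings) or a NEXUS character matrix
#' (via ape) into a [MitoAlignment-class]. Rows keep file order and
#' characters are upper-cased.
#'
#' @param path file path.
#' @param format "fasta" or "nexus".
#' @return a [MitoAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (anyDuplicated(names(ss)))
      stop("label error: duplicate taxon label in ", path)
    seqs <- setNames(as.character(ss), names(ss))
  } else {
    lst <- ape::read.nexus.data(path)
    if (anyDuplicated(names(lst)))
      stop("label error: duplicate taxon label in ", path)
    seqs <- vapply(lst, function(x) paste(x, collapse = ""), "")
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("alignment-length error: ragged rows in ", path,
         " (lengths ", paste(w, collapse = ", "), ")")
  mitoAlignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param aln a [MitoAlignment-class].
#' @param path output file.
#' @export
writeAlignment <- function(aln, path) {
  seqs <- apply(as.matrix(aln), 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Gene annotation rows
#'
#' Builds (or reads) the 6-column gene annotation table: `name`, `start`,
#' `end` (1-based inclusive; `end < start` wraps the circular origin),
#' `strand` (`+`/`-`), `coding` (logical) and `frame` (reading-frame offset
#' 0/1/2). Coding genes need not have length divisible by 3 (terminal
#' incomplete codons occur in mtDNA).
#'
#' @param name gene name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand "+" or "-".
#' @param coding logical; is this a protein-coding gene?
#' @param frame reading frame offset in 0:2.
#' @return one-row data.frame.
#' @export
geneAnnotation <- function(name, start, end, strand = "+", coding = TRUE,
                           frame = 0L) {
  stopifnot(strand %in% c("+", "-"), frame %in% 0:2, start >= 1, end >= 1)
  data.frame(name = name, start = as.integer(start), end = as.integer(end),
             strand = strand, coding = as.logical(coding),
             frame = as.integer(frame), stringsAsFactors = FALSE)
}

#' @rdname geneAnnotation
#' @param path tab-separated annotation file with a header row.
#' @export
readGeneAnnotations <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "start", "end", "strand", "coding", "frame")
  if (!all(need %in% colnames(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  df$coding <- as.logical(df$coding)
  do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    geneAnnotation(df$name[i], df$start[i], df$end[i], df$strand[i],
                   df$coding[i], df$frame[i])))
}

#' @rdname geneAnnotation
#' @param annotations annotation data.frame
#' @export
writeGeneAnnotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## Site indices covered by a gene, in extraction order on the plus strand.
geneSites <- function(gene, n_sites) {
  if (gene$start > n_sites || gene$end > n_sites)
    stop("annotation error: gene '", gene$name, "' outside [1, ",
         n_sites, "]")
  if (gene$end >= gene$start) gene$start:gene$end
  else c(gene$start:n_sites, 1L:gene$end)  # wraps the circular origin
}

#' Extract a single-gene sub-alignment
#'
#' Cuts the columns of one annotated gene out of the full alignment.
#' Wrapped genes (end < start) run through the circular origin; minus-strand
#' genes are reverse-complemented so their codon positions read 5' to 3'.
#' Sites shared with overlapping neighbours are retained in full.
#'
#' @param aln a [MitoAlignment-class].
#' @param gene one-row annotation as from [geneAnnotation()].
#' @return a [MitoAlignment-class] with the gene's columns.
#' @examples
#' aln <- mitoAlignment(c(a = "ACGTACGTAC", b = "ACGAACGTAC"))
#' nSites(extractGene(aln, geneAnnotation("g", 3, 8)))
#' @export
extractGene <- function(aln, gene) {
  if (is.data.frame(gene)) gene <- as.list(gene[1L, ])
  sites <- geneSites(gene, nSites(aln))
  m <- as.matrix(aln)[, sites, drop = FALSE]
  if (gene$strand == "-") {
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m[] <- IUPAC_COMPLEMENT[m]
    m[is.na(m)] <- "N"
  }
  colnames(m) <- NULL
  new("MitoAlignment", seqs = m)
}

#' Concatenate gene alignments
#'
#' Appends sub-alignments column-wise and records each part's site span as
#' a block of the returned partition scheme. All parts must share the same
#' taxon set; taxa are reordered to the first part's order.
#'
#' @param parts list of [MitoAlignment-class] objects.
#' @param names block names; defaults to names(parts).
#' @param scheme_name name for the resulting scheme.
#' @return list with elements `alignment` and `scheme`.
#' @export
concatenateGenes <- function(parts, names = base::names(parts),
                             scheme_name = "concatenation") {
  if (length(parts) == 0L) stop("no parts to concatenate")
  if (is.null(names)) names <- paste0("part", seq_along(parts))
  ref <- taxa(parts[[1L]])
  for (p in parts)
    if (!setequal(taxa(p), ref))
      stop("concatenation error: taxon sets differ between parts")
  mats <- lapply(parts, function(p) as.matrix(p)[ref, , drop = FALSE])
  m <- do.call(cbind, mats)
  colnames(m) <- NULL
  widths <- vapply(mats, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  blocks <- setNames(mapply(function(s, e) s:e, starts, ends,
                            SIMPLIFY = FALSE), names)
  list(alignment = new("MitoAlignment", seqs = m),
       scheme = partitionScheme(scheme_name, blocks))
}

#' Collapse identical sequences into haplotypes
#'
#' Two rows share a haplotype iff their full sequence strings are exactly
#' equal (a gap or N difference separates haplotypes).
#'
#' @param aln a [MitoAlignment-class].
#' @param name partition name recorded in the summary.
#' @return list with `partition_name`, `n_sequences`,
#'   `n_unique_haplotypes` and `collapse_map` (named integer vector,
#'   haplotype ids numbered by first appearance).
#' @export
collapseHaplotypes <- function(aln, name = "alignment") {
  s <- apply(as.matrix(aln), 1L, paste, collapse = "")
  ids <- match(s, unique(s))
  list(partition_name = name,
       n_sequences = nTaxa(aln),
       n_unique_haplotypes = length(unique(s)),
       collapse_map = setNames(ids, taxa(aln)))
}
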