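## Raw (p) and JC69-corrected pairwise distances, saturation tables and
## Neighbor-Joining construction.

ACGT <- c("A", "C", "G", "T")

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites. Sites where either
#' sequence carries a gap or ambiguity code are excluded (pairwise
#' deletion).
#'
#' @param a,b equal-length character vectors or single strings.
#' @return proportion in \[0, 1\].
#' @examples
#' pDistance("ACGT", "ACGA")  # 0.25
#' @export
pDistance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b)) stop("sequences differ in length")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% ACGT & b %in% ACGT
  if (!any(ok))
    stop("undefined-distance error: zero comparable sites")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' JC69 distance correction
#'
#' \eqn{d = -3/4 \log(1 - 4p/3)} substitutions per site. Saturated inputs
#' (\eqn{p \ge 0.75}) return `NA` rather than raising, so saturation can be
#' recorded downstream.
#'
#' @param p proportion of differing sites (vectorized).
#' @return corrected distance(s); `NA` where saturated.
#' @examples
#' jc69Distance(0.1)  # 0.1073256
#' @export
jc69Distance <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- rep(NA_real_, length(p))
  ok <- p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' All pairwise distances of an alignment
#'
#' @param aln a [MitoAlignment-class] with at least 2 taxa.
#' @param model "raw" (p-distance) or "JC69".
#' @return symmetric numeric matrix with taxon dimnames; JC69-saturated
#'   pairs are `NA`.
#' @export
distanceMatrix <- function(aln, model = c("raw", "JC69")) {
  model <- match.arg(model)
  if (nTaxa(aln) < 2L) stop("need at least two taxa")
  m <- as.matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- pDistance(m[i, ], m[j, ])
    v <- if (model == "JC69") jc69Distance(p) else p
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Raw-versus-corrected saturation table
#'
#' One row per unordered taxon pair with the raw p-distance and the JC69
#' correction; pairs past the correction's singularity are flagged
#' saturated. Intended to be plotted corrected versus raw to diagnose
#' multiple hits.
#'
#' @param aln a [MitoAlignment-class] with at least 2 taxa.
#' @return data.frame with columns `taxon_i`, `taxon_j`, `raw`, `jc69`,
#'   `saturated`.
#' @export
saturationTable <- function(aln) {
  if (nTaxa(aln) < 2L) stop("need at least two taxa")
  m <- as.matrix(aln)
  labs <- rownames(m)
  n <- length(labs)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- pDistance(m[i, ], m[j, ])
    d <- jc69Distance(p)
    k <- k + 1L
    rows[[k]] <- data.frame(taxon_i = labs[i], taxon_j = labs[j],
                            raw = p, jc69 = d, saturated = is.na(d),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via ape); negative branch-length
#' estimates are clamped to zero.
#'
#' @param d symmetric numeric matrix with labels (or `dist`).
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("NJ-input error: need at least 3 labels")
  if (any(!is.finite(d)))
    stop("NJ-input error: saturated or undefined entries in the matrix")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
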