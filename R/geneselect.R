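## Informative-gene-subset selection over a genes x clades PP matrix.

#' Genes supporting each clade
#'
#' Per clade, the genes whose clade posterior probability is strictly
#' above the threshold (default 0.6, the minimum support for monophyly
#' used throughout this analysis).
#'
#' @param m a [SupportMatrix-class].
#' @param threshold support threshold in (0, 1).
#' @return named list: clade -> character vector of gene names.
#' @export
supporters <- function(m, threshold = 0.6) {
  stopifnot(threshold > 0, threshold < 1)
  pp <- supportPP(m)
  setNames(lapply(colnames(pp), function(cl)
    rownames(pp)[which(pp[, cl] > threshold)]), colnames(pp))
}

## Deterministic greedy tie-break: compare candidate genes first by their
## sorted-descending PP vector on the newly covered clades, then by lower
## CoV, then lexicographically.
breakTie <- function(cand, newly, pp, cov) {
  ppvec <- setNames(lapply(cand, function(g)
    sort(pp[g, newly[[g]]], decreasing = TRUE)), cand)
  keep <- cand
  len <- max(lengths(ppvec))
  for (i in seq_len(len)) {
    v <- vapply(ppvec[keep], function(x)
      if (length(x) >= i) x[i] else -Inf, 0)
    keep <- keep[v == max(v)]
    if (length(keep) == 1L) return(list(gene = keep, rule = "pp"))
  }
  if (length(cov)) {
    cv <- cov[keep]
    keep2 <- keep[!is.na(cv) & cv == min(cv, na.rm = TRUE)]
    if (length(keep2) == 1L) return(list(gene = keep2, rule = "cov"))
    if (length(keep2) > 1L) keep <- keep2
  }
  list(gene = sort(keep)[1L], rule = "name")
}

#' Select the informative gene subset
#'
#' The two-step selection over a genes x clades support matrix:
#' step 1 keeps every gene that is the sole supporter of some clade;
#' step 2 greedily adds the gene covering the most still-uncovered
#' clades until all clades are covered or no gene helps. Ties are broken
#' first by higher PP on the tied clade(s), then by lower coefficient of
#' rate variation, then by name. The greedy cover is approximate; no
#' minimality is claimed.
#'
#' @param m a [SupportMatrix-class] (CoV recommended for tie-breaks).
#' @param threshold support threshold (default 0.6, strict inequality).
#' @return list with `threshold`, `unique_supporters` (named character:
#'   clade -> gene), `greedy_order` (data.frame of greedy additions),
#'   `selected` (character), `uncovered` (character).
#' @export
selectInformative <- function(m, threshold = 0.6) {
  pp <- supportPP(m)
  sup <- supporters(m, threshold)
  clades <- colnames(pp)

  uniq <- vapply(sup, function(g) length(g) == 1L, TRUE)
  unique_supporters <- vapply(sup[uniq], identity, "")
  selected <- unique(unname(unique_supporters))

  coveredBy <- function(genes)
    clades[vapply(clades, function(cl) any(genes %in% sup[[cl]]), TRUE)]
  covered <- coveredBy(selected)
  greedy <- list()
  repeat {
    uncovered <- setdiff(clades, covered)
    if (!length(uncovered)) break
    newly <- lapply(setdiff(rownames(pp), selected), function(g)
      uncovered[vapply(uncovered, function(cl) g %in% sup[[cl]], TRUE)])
    names(newly) <- setdiff(rownames(pp), selected)
    gains <- lengths(newly)
    if (!length(gains) || max(gains) == 0L) break
    cand <- names(gains)[gains == max(gains)]
    tie <- if (length(cand) == 1L) list(gene = cand, rule = "none")
           else breakTie(cand, newly, pp, m@cov)
    g <- tie$gene
    greedy[[length(greedy) + 1L]] <- data.frame(
      gene = g, n_new = length(newly[[g]]),
      new_clades = paste(newly[[g]], collapse = ";"),
      tiebreak = tie$rule, stringsAsFactors = FALSE)
    selected <- c(selected, g)
    covered <- coveredBy(selected)
  }
  list(threshold = threshold,
       unique_supporters = unique_supporters,
       greedy_order = if (length(greedy)) do.call(rbind, greedy)
                      else data.frame(gene = character(0)),
       selected = selected,
       uncovered = setdiff(clades, covered))
}

#' Validate a concatenated gene subset
#'
#' Pass iff the subset's ensemble supports every clade above the
#' threshold (the final check that the informative subset reproduces
#' mitogenome-level support).
#'
#' @param subset_pp named numeric: clade -> posterior probability from
#'   the concatenated-subset ensemble.
#' @param clades clade names that must be supported.
#' @param threshold support threshold (default 0.6).
#' @return list with `pass` (logical) and `failing` (character).
#' @export
validateSubset <- function(subset_pp, clades, threshold = 0.6) {
  missing <- setdiff(clades, names(subset_pp))
  if (length(missing))
    stop("validation error: missing clade(s): ",
         paste(missing, collapse = ", "))
  failing <- clades[subset_pp[clades] <= threshold]
  list(pass = length(failing) == 0L, failing = unname(failing))
}

#' Read/write a support matrix as CSV
#'
#' Genes in rows, clades in columns; an optional final `cov` column
#' carries the per-gene coefficient of rate variation.
#'
#' @param path CSV file.
#' @return a [SupportMatrix-class].
#' @export
readSupportMatrix <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  cov <- numeric(0)
  if ("cov" %in% colnames(df)) {
    cov <- setNames(df$cov, rownames(df))
    df <- df[, setdiff(colnames(df), "cov"), drop = FALSE]
  }
  supportMatrix(as.matrix(df), cov)
}

#' @rdname readSupportMatrix
#' @param m a [SupportMatrix-class].
#' @export
writeSupportMatrix <- function(m, path) {
  df <- as.data.frame(supportPP(m))
  if (length(m@cov)) df$cov <- m@cov[rownames(df)]
  write.csv(df, path, row.names = TRUE)
  invisible(path)
}
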