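#' @import methods
#' @importFrom stats aov acf coef cor density dlnorm lm median optim plnorm
#'   pnorm qlnorm quantile rbinom rgamma rlnorm rnorm runif sd setNames var pf
#' @importFrom utils read.table write.table read.csv write.csv head tail
NULL

#' Multiple sequence alignment of mitochondrial sequences
#'
#' A character matrix (one row per taxon, one column per alignment site)
#' holding upper-case nucleotides, gaps (`-`) and IUPAC ambiguity codes.
#' Row names are the taxon labels and must be unique.
#'
#' @slot seqs character matrix, rows = taxa, columns = sites.
#' @seealso [mitoAlignment()], [readAlignment()]
#' @export
setClass("MitoAlignment", representation(seqs = "matrix"))

setValidity("MitoAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (ncol(m) < 1L) return("alignment must have at least one site")
  if (nrow(m) < 1L) return("alignment must have at least one taxon")
  if (is.null(rownames(m))) return("taxon labels (rownames) required")
  if (anyDuplicated(rownames(m))) return("duplicate taxon labels")
  if (any(nchar(m) != 1L)) return("matrix cells must be single characters")
  TRUE
})

#' Construct a MitoAlignment
#'
#' @param x named character vector of equal-length sequence strings, or a
#'   character matrix of single characters with taxon rownames.
#' @return a [MitoAlignment-class] object.
#' @examples
#' aln <- mitoAlignment(c(a = "ACGT", b = "ACGA"))
#' nSites(aln)
#' @export
mitoAlignment <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x))) stop("sequences must be named")
    w <- unique(nchar(x))
    if (length(w) != 1L)
      stop("alignment-length error: sequences have unequal lengths (",
           paste(w, collapse = ", "), ")")
    m <- do.call(rbind, strsplit(as.character(x), ""))
    rownames(m) <- names(x)
  }
  m[] <- toupper(m)
  new("MitoAlignment", seqs = m)
}

#' @describeIn mitoAlignment number of alignment columns
#' @param aln a MitoAlignment
#' @export
nSites <- function(aln) ncol(aln@seqs)

#' @describeIn mitoAlignment number of taxa
#' @export
nTaxa <- function(aln) nrow(aln@seqs)

#' @describeIn mitoAlignment taxon labels in row order
#' @export
taxa <- function(aln) rownames(aln@seqs)

#' @export
setMethod("as.matrix", "MitoAlignment", function(x, ...) x@seqs)

setMethod("show", "MitoAlignment", function(object) {
  cat("MitoAlignment:", nTaxa(object), "taxa x", nSites(object), "sites\n")
})

#' Partitioning scheme over alignment columns
#'
#' Named, ordered blocks of 1-based site indices. Blocks may overlap only
#' where gene annotations overlap (shared sites are kept in every gene that
#' contains them).
#'
#' @slot name scheme name.
#' @slot blocks named list of integer vectors of site indices.
#' @export
setClass("PartitionScheme",
         representation(name = "character", blocks = "list"))

setValidity("PartitionScheme", function(object) {
  if (length(object@blocks) == 0L) return("scheme needs at least one block")
  if (is.null(names(object@blocks)) || anyDuplicated(names(object@blocks)))
    return("blocks must have unique names")
  for (b in object@blocks) {
    if (length(b) == 0L) return("empty block")
    if (anyDuplicated(b)) return("duplicate site indices within a block")
    if (any(b < 1L)) return("site indices must be >= 1")
  }
  TRUE
})

#' @rdname PartitionScheme-class
#' @param name scheme name
#' @param blocks named list of integer site-index vectors
#' @export
partitionScheme <- function(name, blocks)
  new("PartitionScheme", name = name,
      blocks = lapply(blocks, function(b) as.integer(b)))

#' @rdname PartitionScheme-class
#' @param scheme a PartitionScheme
#' @export
nBlocks <- function(scheme) length(scheme@blocks)

#' @rdname PartitionScheme-class
#' @export
blocks <- function(scheme) scheme@blocks

setMethod("show", "PartitionScheme", function(object) {
  cat("PartitionScheme '", object@name, "': ", nBlocks(object),
      " block(s), ", sum(lengths(object@blocks)), " sites\n", sep = "")
})

#' Posterior sample of rooted trees
#'
#' An ordered collection of trees (post-thinning MCMC states) over a shared
#' taxon set, with optional per-sample scalars (posterior log density, log
#' likelihood). Sample order is preserved so burn-in removal is meaningful.
#'
#' @slot trees list of `ape::phylo` trees.
#' @slot stats data.frame of per-sample scalars (0 columns allowed); if
#'   non-empty it has one row per tree.
#' @export
setClass("TreeEnsemble",
         representation(trees = "list", stats = "data.frame"))

setValidity("TreeEnsemble", function(object) {
  if (length(object@trees) == 0L) return("ensemble is empty")
  if (!all(vapply(object@trees, inherits, TRUE, "phylo")))
    return("all samples must be 'phylo' trees")
  tx <- sort(object@trees[[1L]]$tip.label)
  for (t in object@trees)
    if (!identical(sort(t$tip.label), tx))
      return("ensemble error: samples have inconsistent taxon sets")
  if (ncol(object@stats) > 0L && nrow(object@stats) != length(object@trees))
    return("stats rows must match the number of samples")
  TRUE
})

#' @rdname TreeEnsemble-class
#' @param trees list of `phylo` trees (or a `multiPhylo`)
#' @param stats optional data.frame of per-sample scalars
#' @export
treeEnsemble <- function(trees, stats = data.frame()) {
  trees <- unclass(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  new("TreeEnsemble", trees = trees, stats = stats)
}

#' @rdname TreeEnsemble-class
#' @param e a TreeEnsemble
#' @export
nSamples <- function(e) length(e@trees)

#' @rdname TreeEnsemble-class
#' @export
ensembleTrees <- function(e) e@trees

#' @rdname TreeEnsemble-class
#' @export
ensembleStats <- function(e) e@stats

#' @rdname TreeEnsemble-class
#' @export
ensembleTaxa <- function(e) sort(e@trees[[1L]]$tip.label)

setMethod("show", "TreeEnsemble", function(object) {
  cat("TreeEnsemble:", nSamples(object), "samples,",
      length(object@trees[[1L]]$tip.label), "taxa")
  if (ncol(object@stats) > 0L)
    cat("; stats:", paste(colnames(object@stats), collapse = ", "))
  cat("\n")
})

#' MCMC trace log
#'
#' Named real-valued sample columns indexed by a strictly increasing state
#' counter, as written by Bayesian phylogenetics samplers (tab-separated,
#' `#` comment lines, first column `state`).
#'
#' @slot state numeric vector of state indices (strictly increasing).
#' @slot samples data.frame of named numeric columns.
#' @export
setClass("TraceLog", representation(state = "numeric", samples = "data.frame"))

setValidity("TraceLog", function(object) {
  if (nrow(object@samples) != length(object@state))
    return("column lengths differ from state index length")
  if (length(object@state) > 1L && any(diff(object@state) <= 0))
    return("state indices must be strictly increasing")
  if (!all(vapply(object@samples, is.numeric, TRUE)))
    return("all trace columns must be numeric")
  TRUE
})

#' @rdname TraceLog-class
#' @param state numeric state indices
#' @param samples data.frame of numeric columns
#' @export
traceLog <- function(state, samples)
  new("TraceLog", state = as.numeric(state),
      samples = as.data.frame(samples))

#' @rdname TraceLog-class
#' @param trace a TraceLog
#' @param column column name
#' @export
traceColumn <- function(trace, column) {
  if (!column %in% colnames(trace@samples))
    stop("no trace column named '", column, "'")
  trace@samples[[column]]
}

#' @rdname TraceLog-class
#' @export
traceColumns <- function(trace) colnames(trace@samples)

setMethod("show", "TraceLog", function(object) {
  cat("TraceLog:", length(object@state), "states,",
      ncol(object@samples), "columns\n")
})

#' Nucleotide substitution model
#'
#' JC69, K80, HKY or GTR, optionally with discrete-gamma rate variation
#' (equal-probability categories, category means) and a proportion of
#' invariant sites. The rate matrix is scaled so the expected substitution
#' rate is 1, making branch lengths expected substitutions per site.
#'
#' @slot kind one of "JC69", "K80", "HKY", "GTR".
#' @slot kappa transition/transversion rate ratio (K80, HKY).
#' @slot rates six GTR exchangeabilities (AC, AG, AT, CG, CT, GT; GT = 1).
#' @slot baseFreqs equilibrium base frequencies (A, C, G, T).
#' @slot gammaShape gamma shape; length 0 when absent.
#' @slot nCat number of discrete gamma categories.
#' @slot pInv proportion of invariant sites; length 0 when absent.
#' @export
setClass("SubstModel",
         representation(kind = "character", kappa = "numeric",
                        rates = "numeric", baseFreqs = "numeric",
                        gammaShape = "numeric", nCat = "integer",
                        pInv = "numeric"))

setValidity("SubstModel", function(object) {
  if (!object@kind %in% c("JC69", "K80", "HKY", "GTR"))
    return("unknown model kind")
  if (length(object@baseFreqs) != 4L ||
      abs(sum(object@baseFreqs) - 1) > 1e-12 || any(object@baseFreqs <= 0))
    return("base frequencies must be 4 positive values summing to 1")
  if (object@kind %in% c("K80", "HKY") &&
      (length(object@kappa) != 1L || object@kappa <= 0))
    return("kappa must be a positive scalar for K80/HKY")
  if (object@kind == "GTR" &&
      (length(object@rates) != 6L || any(object@rates < 0)))
    return("GTR needs 6 nonnegative exchangeabilities")
  if (length(object@gammaShape) == 1L && object@gammaShape <= 0)
    return("gamma shape must be positive")
  if (length(object@pInv) == 1L &&
      (object@pInv < 0 || object@pInv >= 1))
    return("p_invariant must lie in [0, 1)")
  TRUE
})

#' Construct a substitution model
#'
#' @param kind "JC69", "K80", "HKY" or "GTR".
#' @param kappa transition/transversion ratio (K80/HKY; default 2).
#' @param rates six exchangeabilities in order AC, AG, AT, CG, CT, GT
#'   (GTR only; GT conventionally 1).
#' @param baseFreqs base frequencies (A, C, G, T); forced to 1/4 for
#'   JC69/K80.
#' @param gammaShape optional gamma shape for among-site rate variation.
#' @param nCat number of discrete gamma categories (default 4).
#' @param pInv optional proportion of invariant sites.
#' @return a [SubstModel-class].
#' @examples
#' substModel("HKY", kappa = 4, baseFreqs = c(0.3, 0.2, 0.2, 0.3))
#' @export
substModel <- function(kind, kappa = 2, rates = rep(1, 6),
                       baseFreqs = rep(0.25, 4), gammaShape = NULL,
                       nCat = 4L, pInv = NULL) {
  kind <- match.arg(kind, c("JC69", "K80", "HKY", "GTR"))
  if (kind %in% c("JC69", "K80")) baseFreqs <- rep(0.25, 4)
  baseFreqs <- baseFreqs / sum(baseFreqs)
  new("SubstModel", kind = kind, kappa = as.numeric(kappa),
      rates = as.numeric(rates), baseFreqs = as.numeric(baseFreqs),
      gammaShape = if (is.null(gammaShape)) numeric(0) else
        as.numeric(gammaShape),
      nCat = as.integer(nCat),
      pInv = if (is.null(pInv)) numeric(0) else as.numeric(pInv))
}

setMethod("show", "SubstModel", function(object) {
  tag <- object@kind
  if (length(object@pInv)) tag <- paste0(tag, "+I")
  if (length(object@gammaShape)) tag <- paste0(tag, "+G")
  cat("SubstModel:", tag, "\n")
})

#' Fitted substitution model with BIC
#'
#' @slot model the fitted [SubstModel-class].
#' @slot lnL maximized log-likelihood.
#' @slot k number of free parameters (substitution parameters, estimated
#'   frequencies, gamma shape, p_invariant and the single branch-length
#'   multiplier).
#' @slot n sample size used in the BIC penalty (alignment sites by default).
#' @slot bic \eqn{-2 lnL + k ln(n)}.
#' @slot scale fitted branch-length multiplier applied to the guide tree.
#' @slot warnings character vector (e.g. kappa-at-bound).
#' @export
setClass("ModelFit",
         representation(model = "SubstModel", lnL = "numeric", k = "numeric",
                        n = "numeric", bic = "numeric", scale = "numeric",
                        warnings = "character"))

setValidity("ModelFit", function(object) {
  if (abs(object@bic - (-2 * object@lnL + object@k * log(object@n))) > 1e-6)
    return("bic must equal -2*lnL + k*ln(n)")
  TRUE
})

setMethod("show", "ModelFit", function(object) {
  show(object@model)
  cat(sprintf("  lnL = %.4f, k = %d, n = %d, BIC = %.4f\n",
              object@lnL, as.integer(object@k), as.integer(object@n),
              object@bic))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

#' Lognormal node-age calibration prior
#'
#' @slot name calibration name.
#' @slot meanlog lognormal log-mean (ages in My after subtracting offset).
#' @slot sdlog lognormal log-sd (> 0).
#' @slot offset hard lower bound in My added to the lognormal variate.
#' @slot clade taxon labels of the calibrated clade (may be empty).
#' @export
setClass("CalibrationPrior",
         representation(name = "character", meanlog = "numeric",
                        sdlog = "numeric", offset = "numeric",
                        clade = "character"))

setValidity("CalibrationPrior", function(object) {
  if (object@sdlog <= 0) return("sdlog must be > 0")
  TRUE
})

#' @rdname CalibrationPrior-class
#' @param name calibration name
#' @param meanlog,sdlog lognormal parameters on the log scale
#' @param offset age offset in My (default 0)
#' @param clade optional taxon labels of the calibrated clade
#' @export
calibrationPrior <- function(name, meanlog, sdlog, offset = 0,
                             clade = character(0))
  new("CalibrationPrior", name = name, meanlog = as.numeric(meanlog),
      sdlog = as.numeric(sdlog), offset = as.numeric(offset), clade = clade)

setMethod("show", "CalibrationPrior", function(object) {
  cat(sprintf("CalibrationPrior '%s': LogNormal(meanlog=%.4g, sdlog=%.4g)",
              object@name, object@meanlog, object@sdlog))
  if (object@offset != 0) cat(sprintf(" + offset %.4g My", object@offset))
  cat("\n")
})

#' Genes-by-clades posterior-probability support matrix
#'
#' Rows are genes (partitions), columns are clades; entries are clade
#' posterior probabilities. An optional per-gene coefficient of rate
#' variation is carried for tie-breaking during gene selection.
#'
#' @slot pp numeric matrix of probabilities, genes x clades.
#' @slot cov named numeric vector of per-gene CoV (length 0 if absent).
#' @export
setClass("SupportMatrix",
         representation(pp = "matrix", cov = "numeric"))

setValidity("SupportMatrix", function(object) {
  if (!is.numeric(object@pp)) return("pp must be numeric")
  if (any(object@pp < 0 | object@pp > 1, na.rm = TRUE))
    return("posterior probabilities must lie in [0, 1]")
  if (is.null(rownames(object@pp)) || is.null(colnames(object@pp)))
    return("pp needs gene rownames and clade colnames")
  if (length(object@cov) &&
      !all(rownames(object@pp) %in% names(object@cov)))
    return("cov must be named for every gene")
  TRUE
})

#' @rdname SupportMatrix-class
#' @param pp genes x clades probability matrix with dimnames
#' @param cov optional named per-gene coefficient of rate variation
#' @export
supportMatrix <- function(pp, cov = numeric(0)) {
  if (length(cov) && is.null(names(cov))) names(cov) <- rownames(pp)
  new("SupportMatrix", pp = pp, cov = cov)
}

#' @rdname SupportMatrix-class
#' @param m a SupportMatrix
#' @export
supportGenes <- function(m) rownames(m@pp)

#' @rdname SupportMatrix-class
#' @export
supportClades <- function(m) colnames(m@pp)

#' @rdname SupportMatrix-class
#' @export
supportPP <- function(m) m@pp

setMethod("show", "SupportMatrix", function(object) {
  cat("SupportMatrix:", nrow(object@pp), "genes x", ncol(object@pp),
      "clades", if (length(object@cov)) "(with CoV)" else "", "\n")
})
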