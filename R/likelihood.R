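## Felsenstein-pruning log-likelihood for JC69/K80/HKY/GTR with discrete
## gamma (+G) and invariant sites (+I). The rate matrix is scaled to mean
## rate 1 so branch lengths are expected substitutions per site.

IUPAC_STATES <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
  "?" = c("A", "C", "G", "T"))

## 4 x nchar indicator matrix: rows A,C,G,T
iupacIndicator <- local({
  codes <- names(IUPAC_STATES)
  m <- sapply(IUPAC_STATES, function(s) as.numeric(ACGT %in% s))
  rownames(m) <- ACGT
  m
})

## Exchangeability vector (AC, AG, AT, CG, CT, GT) for any model kind.
modelExchangeabilities <- function(model) {
  switch(model@kind,
         JC69 = rep(1, 6),
         K80 = c(1, model@kappa, 1, 1, model@kappa, 1),
         HKY = c(1, model@kappa, 1, 1, model@kappa, 1),
         GTR = model@rates)
}

## GTR-family rate matrix scaled to mean rate 1.
rateMatrix <- function(model) {
  r <- modelExchangeabilities(model)
  f <- model@baseFreqs
  Q <- matrix(0, 4, 4, dimnames = list(ACGT, ACGT))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    Q[i, j] <- r[k] * f[j]
    Q[j, i] <- r[k] * f[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q / mu
}

## Eigen system of a reversible Q via symmetrization.
eigenQ <- function(Q, f) {
  s <- sqrt(f)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / s) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(s)
  list(values = e$values, U = U, Uinv = Uinv)
}

transitionProb <- function(eig, t) {
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  P
}

#' Mean rates of equal-probability discrete gamma categories
#'
#' @param shape gamma shape (mean 1 parameterization).
#' @param nCat number of categories.
#' @return numeric vector of category rates with mean 1.
#' @export
discreteGammaRates <- function(shape, nCat = 4L) {
  b <- stats::qgamma(seq(0, 1, length.out = nCat + 1L), shape, rate = shape)
  up <- stats::pgamma(b[-1L], shape + 1, rate = shape)
  lo <- stats::pgamma(b[-(nCat + 1L)], shape + 1, rate = shape)
  r <- nCat * (up - lo)
  r / mean(r)  # guard tiny numerical drift
}

## Site-rate mixture (rates and weights) implied by +G / +I flags.
rateMixture <- function(model) {
  pInv <- if (length(model@pInv)) model@pInv else 0
  if (length(model@gammaShape)) {
    r <- discreteGammaRates(model@gammaShape, model@nCat)
    rates <- r / (1 - pInv)
    w <- rep((1 - pInv) / model@nCat, model@nCat)
  } else {
    rates <- 1 / (1 - pInv)
    w <- 1 - pInv
  }
  list(rates = rates, weights = w, pInv = pInv)
}

## Compress alignment columns into unique patterns with weights,
## restricted and reordered to `taxa`.
sitePatterns <- function(aln, taxa) {
  m <- as.matrix(aln)[taxa, , drop = FALSE]
  key <- apply(m, 2L, paste, collapse = "")
  u <- !duplicated(key)
  list(patterns = m[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]))
}

## Conditional likelihoods at the root for one category rate.
rootPartials <- function(tree, tipInd, scaledLen, eig, rate) {
  ntip <- length(tipInd)
  nnode <- tree$Nnode
  npat <- ncol(tipInd[[1L]])
  part <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) part[[i]] <- tipInd[[i]]
  Ps <- lapply(scaledLen, function(len)
    if (rate == 0) diag(4) else transitionProb(eig, len * rate))
  po <- ape::postorder(tree)
  for (ei in po) {
    par <- tree$edge[ei, 1L]; chl <- tree$edge[ei, 2L]
    contrib <- Ps[[ei]] %*% part[[chl]]
    part[[par]] <- if (is.null(part[[par]])) contrib
                   else part[[par]] * contrib
  }
  part[[ntip + 1L]]
}

#' Phylogenetic log-likelihood by pruning
#'
#' Sums, over compressed site patterns, the log likelihood of the
#' alignment on the given tree under the substitution model, with
#' discrete-gamma and invariant-site mixtures when the model carries
#' them. Gaps and ambiguity codes contribute a partial likelihood of 1
#' over their compatible states.
#'
#' @param aln a [MitoAlignment-class]; must contain all tree tips.
#' @param tree a `phylo` with branch lengths in expected substitutions
#'   per site.
#' @param model a [SubstModel-class].
#' @param scale optional multiplier applied to every branch length.
#' @return log-likelihood (scalar).
## Precompute everything likelihood evaluations share: compressed site
## patterns, per-tip indicator matrices and the post-order edge list.
likelihoodData <- function(aln, tree) {
  if (!all(tree$tip.label %in% taxa(aln)))
    stop("tree leaves must be a subset of alignment taxa")
  if (nSites(aln) == 0L) stop("zero-length alignment")
  sp <- sitePatterns(aln, tree$tip.label)
  pat <- sp$patterns
  bad <- !pat %in% names(IUPAC_STATES)
  if (any(bad)) stop("unknown residue(s): ",
                     paste(unique(pat[bad]), collapse = ", "))
  tipInd <- lapply(seq_len(nrow(pat)), function(i)
    iupacIndicator[, pat[i, ], drop = FALSE])
  list(tree = tree, tipInd = tipInd, weights = sp$weights)
}

likelihoodFromData <- function(dat, model, scale = 1) {
  f <- model@baseFreqs
  eig <- eigenQ(rateMatrix(model), f)
  mix <- rateMixture(model)
  scaledLen <- dat$tree$edge.length * scale
  siteL <- 0
  for (k in seq_along(mix$rates)) {
    rp <- rootPartials(dat$tree, dat$tipInd, scaledLen, eig,
                       mix$rates[k])
    siteL <- siteL + mix$weights[k] * as.numeric(f %*% rp)
  }
  if (mix$pInv > 0) {
    rp0 <- rootPartials(dat$tree, dat$tipInd, scaledLen, eig, 0)
    siteL <- siteL + mix$pInv * as.numeric(f %*% rp0)
  }
  lnL <- sum(dat$weights * log(siteL))
  if (!is.finite(lnL)) stop("numerical error: non-finite log-likelihood")
  lnL
}

#' @export
logLikelihood <- function(aln, tree, model, scale = 1) {
  likelihoodFromData(likelihoodData(aln, tree), model, scale)
}

## Empirical base frequencies (ACGT only), with a floor to stay positive.
empiricalBaseFreqs <- function(aln) {
  m <- as.matrix(aln)
  cnt <- vapply(ACGT, function(b) sum(m == b), 0)
  cnt <- cnt + 0.5  # pseudo-count keeps degenerate data usable
  cnt / sum(cnt)
}
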