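## Maximum-likelihood model fitting on a fixed guide tree and BIC-based
## model selection over the JC69/K80/HKY/GTR (+I, +G) candidate space.

KAPPA_CAP <- 1e4

#' Bayesian Information Criterion
#'
#' @param lnL log-likelihood.
#' @param k free-parameter count.
#' @param n sample size (alignment sites by default convention).
#' @return \eqn{-2 lnL + k ln(n)}.
#' @export
bic <- function(lnL, k, n) -2 * lnL + k * log(n)

## Free-parameter layout for one candidate; all positives on log scale,
## pInv on logit scale.
paramLayout <- function(kind, gamma, inv) {
  nm <- "logScale"
  if (kind %in% c("K80", "HKY")) nm <- c(nm, "logKappa")
  if (kind == "GTR") nm <- c(nm, paste0("logR", 1:5))
  if (gamma) nm <- c(nm, "logShape")
  if (inv) nm <- c(nm, "logitPInv")
  nm
}

buildModel <- function(kind, theta, freqs, gamma, inv, nCat) {
  kappa <- if ("logKappa" %in% names(theta)) exp(theta[["logKappa"]]) else 2
  rates <- if (kind == "GTR")
    c(exp(theta[paste0("logR", 1:5)]), 1) else rep(1, 6)
  substModel(kind, kappa = kappa, rates = rates, baseFreqs = freqs,
             gammaShape = if (gamma) exp(theta[["logShape"]]) else NULL,
             nCat = nCat,
             pInv = if (inv) stats::plogis(theta[["logitPInv"]]) else NULL)
}

## Count of free parameters: substitution parameters + estimated
## frequencies + shape + pInv + the single branch-length multiplier.
freeParamCount <- function(kind, gamma, inv) {
  k <- 1  # branch-length multiplier
  k <- k + switch(kind, JC69 = 0, K80 = 1, HKY = 1 + 3, GTR = 5 + 3)
  if (gamma) k <- k + 1
  if (inv) k <- k + 1
  k
}

#' Fit a substitution model on a guide tree
#'
#' Optimizes the model's free parameters (kappa or GTR exchangeabilities,
#' gamma shape, proportion of invariant sites) together with a single
#' branch-length multiplier on the guide tree, by bounded quasi-Newton
#' with three spread restarts (tolerance 1e-6 on lnL). Base frequencies
#' are empirical. Kappa is capped at 1e4; a binding cap raises a
#' `kappa-at-bound` warning entry.
#'
#' @param aln a [MitoAlignment-class].
#' @param tree guide tree (`phylo`); by default build one with
#'   [njTree()] on JC69 distances.
#' @param kind "JC69", "K80", "HKY" or "GTR".
#' @param gamma add discrete-gamma rate variation?
#' @param inv add a proportion of invariant sites?
#' @param nCat gamma categories (default 4).
#' @param n BIC sample size; defaults to the number of alignment sites
#'   (pass e.g. 1000 to reproduce tool conventions that fix it).
#' @return a [ModelFit-class].
#' @export
fitModel <- function(aln, tree = NULL, kind = "HKY", gamma = FALSE,
                     inv = FALSE, nCat = 4L, n = nSites(aln)) {
  kind <- match.arg(kind, c("JC69", "K80", "HKY", "GTR"))
  if (is.null(tree)) tree <- guideTree(aln)
  freqs <- if (kind %in% c("JC69", "K80")) rep(0.25, 4)
           else empiricalBaseFreqs(aln)
  layout <- paramLayout(kind, gamma, inv)
  dat <- likelihoodData(aln, tree)
  negLL <- function(theta) {
    names(theta) <- layout
    m <- buildModel(kind, theta, freqs, gamma, inv, nCat)
    -likelihoodFromData(dat, m, scale = exp(theta[["logScale"]]))
  }
  lower <- setNames(rep(-12, length(layout)), layout)
  upper <- setNames(rep(12, length(layout)), layout)
  lower["logScale"] <- -15; upper["logScale"] <- 8
  if ("logKappa" %in% layout) upper["logKappa"] <- log(KAPPA_CAP)
  if ("logitPInv" %in% layout) { lower["logitPInv"] <- -12
                                 upper["logitPInv"] <- 5 }
  start0 <- setNames(rep(0, length(layout)), layout)
  if (gamma) start0["logShape"] <- log(0.5)
  if (inv) start0["logitPInv"] <- -1
  best <- NULL
  fails <- character(0)
  for (s0 in c(-1, 0, 1)) {  # spread restarts on the branch multiplier
    start <- start0
    start["logScale"] <- s0
    fit <- tryCatch(
      optim(start, negLL, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(factr = 1e7, maxit = 300)),
      error = function(e) e)
    if (inherits(fit, "error")) { fails <- c(fails, conditionMessage(fit))
                                  next }
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best))
    stop("fit error: optimizer failed for all restarts (",
         paste(unique(fails), collapse = "; "), ")")
  theta <- best$par
  names(theta) <- layout
  warnings <- character(0)
  if ("logKappa" %in% layout &&
      theta[["logKappa"]] >= log(KAPPA_CAP) - 1e-6) {
    warnings <- c(warnings, "kappa-at-bound")
  }
  model <- buildModel(kind, theta, freqs, gamma, inv, nCat)
  lnL <- -best$value
  k <- freeParamCount(kind, gamma, inv)
  new("ModelFit", model = model, lnL = lnL, k = k, n = as.numeric(n),
      bic = bic(lnL, k, n), scale = exp(theta[["logScale"]]),
      warnings = warnings)
}

#' Default NJ guide tree on JC69 distances
#'
#' @param aln a [MitoAlignment-class] with >= 3 taxa.
#' @return an unrooted `phylo`.
#' @export
guideTree <- function(aln) {
  d <- distanceMatrix(aln, "JC69")
  if (any(!is.finite(d)))
    stop("guide tree: saturated JC69 distances; supply a tree explicitly")
  njTree(d)
}

#' The 16-candidate model space
#'
#' JC69, K80, HKY and GTR, each plain and with +I, +G and +I+G.
#'
#' @return data.frame with columns `kind`, `gamma`, `inv`.
#' @export
defaultCandidates <- function() {
  g <- expand.grid(kind = c("JC69", "K80", "HKY", "GTR"),
                   gamma = c(FALSE, TRUE), inv = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  g[order(match(g$kind, c("JC69", "K80", "HKY", "GTR")), g$inv, g$gamma), ]
}

modelTag <- function(kind, gamma, inv)
  paste0(kind, if (inv) "+I" else "", if (gamma) "+G" else "")

#' BIC model selection
#'
#' Fits every candidate on the guide tree and returns the fit with the
#' smallest BIC. The full ranking (model, lnL, k, n, BIC, delta-BIC,
#' warnings) is attached as attribute `"ranking"`.
#'
#' @param aln a [MitoAlignment-class].
#' @param candidates data.frame as from [defaultCandidates()].
#' @param tree guide tree; defaults to [guideTree()].
#' @param n BIC sample size override (defaults to alignment sites).
#' @return the best [ModelFit-class] (attribute `ranking`: data.frame).
#' @export
selectModel <- function(aln, candidates = defaultCandidates(),
                        tree = NULL, n = nSites(aln)) {
  if (nrow(candidates) < 1L) stop("need at least one candidate")
  if (is.null(tree)) tree <- guideTree(aln)
  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    tag <- modelTag(cand$kind, cand$gamma, cand$inv)
    fit <- tryCatch(
      fitModel(aln, tree, cand$kind, cand$gamma, cand$inv, n = n),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[tag]] <- data.frame(model = tag, lnL = NA, k = NA, n = n,
                                bic = NA, warnings = conditionMessage(fit))
      next
    }
    fits[[tag]] <- fit
    rows[[tag]] <- data.frame(model = tag, lnL = fit@lnL, k = fit@k, n = n,
                              bic = fit@bic,
                              warnings = paste(fit@warnings,
                                               collapse = ";"))
  }
  if (!length(fits)) stop("selection error: all candidates failed")
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$bic), ]
  ranking$delta_bic <- ranking$bic - min(ranking$bic, na.rm = TRUE)
  rownames(ranking) <- NULL
  best <- fits[[ranking$model[1L]]]
  attr(best, "ranking") <- ranking
  best
}

#' Write a model-selection report as CSV
#'
#' @param fit result of [selectModel()].
#' @param path output CSV file.
#' @export
writeModelReport <- function(fit, path) {
  rk <- attr(fit, "ranking")
  if (is.null(rk)) stop("fit has no ranking attribute")
  write.csv(rk, path, row.names = FALSE)
  invisible(path)
}
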