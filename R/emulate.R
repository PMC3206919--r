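## Emulated posterior tree ensembles. Full-scale Bayesian MCMC runs
## are out of scope; downstream statistics only need an ensemble whose
## clade frequencies track signal strength and whose node ages scatter
## around the truth, which a column bootstrap + NJ with lognormal age
## jitter provides.

## Age of the MRCA of `taxaSet` in `tree`, given precomputed node ages.
mrcaAge <- function(tree, ages, taxaSet) {
  idx <- match(taxaSet, tree$tip.label)
  if (length(idx) == length(tree$tip.label))
    return(max(ages))
  ages[ape::getMRCA(tree, idx)]
}

## Turn a rooted topology into an ultrametric tree by assigning each
## internal node the (jittered) age of the true tree's MRCA of its clade,
## then clamping so children sit below parents.
ultrametricize <- function(tree, true_tree, true_ages, age_log_sd) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  h <- numeric(nn)
  kk <- cladeKeys(tree)
  for (j in seq_len(nrow(kk))) {
    S <- strsplit(kk$key[j], "|", fixed = TRUE)[[1L]]
    a <- mrcaAge(true_tree, true_ages, S)
    jit <- exp(rnorm(1L, -age_log_sd^2 / 2, age_log_sd))
    h[kk$node[j]] <- a * jit
  }
  ord <- rev(ape::postorder(tree))
  for (ei in ord) {
    par <- tree$edge[ei, 1L]; chl <- tree$edge[ei, 2L]
    if (chl > ntip && h[chl] >= h[par]) h[chl] <- h[par] * (1 - 1e-9)
  }
  tree$edge.length <- h[tree$edge[, 1L]] - h[tree$edge[, 2L]]
  tree
}

#' Emulate a posterior tree ensemble and trace log
#'
#' Topologies come from a nonparametric bootstrap of alignment columns
#' followed by NJ on JC69 distances (clade frequencies thus track the
#' signal strength of the data), midpoint-rooted; each sample is made
#' ultrametric by assigning node ages jittered lognormally (log-sd
#' `age_log_sd`) around the true tree's ages for the matching clades.
#' The trace log carries, per sample, the JC69 log-likelihood of the
#' data on the sampled tree (used as the posterior-density scalar), a
#' mean-rate column, and the MRCA age of every named clade.
#'
#' @param aln a [MitoAlignment-class].
#' @param true_tree rooted ultrametric `phylo` (time in My) over the
#'   alignment's taxa.
#' @param ensemble_size number of samples (>= 100).
#' @param age_log_sd log-scale sd of the node-age jitter.
#' @param seed RNG seed.
#' @param clades optional named list of taxon sets whose MRCA ages are
#'   logged; defaults to every internal clade of `true_tree` (named
#'   `cladeK` by node number).
#' @param clock_mean substitutions/site/My used to convert time branch
#'   lengths when scoring the likelihood.
#' @return list with `ensemble` (a [TreeEnsemble-class] with `posterior`
#'   and `likelihood` stats) and `trace` (a [TraceLog-class]).
#' @export
emulatePosterior <- function(aln, true_tree, ensemble_size = 500L,
                             age_log_sd = 0.1, seed = 1L, clades = NULL,
                             clock_mean = 5e-3) {
  stopifnot(ensemble_size >= 100L)
  if (!setequal(taxa(aln), true_tree$tip.label))
    stop("alignment and true tree must share taxa")
  true_ages <- nodeAges(true_tree)
  if (is.null(clades)) {
    kk <- cladeKeys(true_tree)
    clades <- lapply(kk$key, strsplit, split = "|", fixed = TRUE)
    clades <- lapply(clades, `[[`, 1L)
    names(clades) <- paste0("clade", kk$node)
  }
  m <- as.matrix(aln)
  ns <- ncol(m)
  labs <- rownames(m)
  nt <- length(labs)
  jc <- substModel("JC69")
  ## integer-coded matrix (NA for gaps/ambiguities) for fast bootstrap
  ## distances, and one shared pattern compression for the likelihoods
  X <- matrix(match(m, ACGT), nt, ns, dimnames = dimnames(m))
  sp <- sitePatterns(aln, labs)
  tipIndByName <- setNames(lapply(seq_len(nt), function(i)
    iupacIndicator[, sp$patterns[i, ], drop = FALSE]), labs)
  pairs <- which(upper.tri(matrix(0, nt, nt)), arr.ind = TRUE)
  set.seed(seed)
  trees <- vector("list", ensemble_size)
  lnl <- numeric(ensemble_size)
  cladeAges <- matrix(NA_real_, ensemble_size, length(clades),
                      dimnames = list(NULL, names(clades)))
  meanRate <- clock_mean * exp(rnorm(ensemble_size, -age_log_sd^2 / 2,
                                     age_log_sd))
  for (b in seq_len(ensemble_size)) {
    Xb <- X[, sample.int(ns, ns, replace = TRUE), drop = FALSE]
    d <- matrix(0, nt, nt, dimnames = list(labs, labs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      ok <- !is.na(Xb[i, ]) & !is.na(Xb[j, ])
      p <- sum(Xb[i, ok] != Xb[j, ok]) / sum(ok)
      dj <- jc69Distance(p)
      d[i, j] <- d[j, i] <- if (is.na(dj)) p else dj
    }
    topo <- phangorn::midpoint(njTree(d))
    tr <- ultrametricize(topo, true_tree, true_ages, age_log_sd)
    trees[[b]] <- tr
    dat <- list(tree = tr, tipInd = tipIndByName[tr$tip.label],
                weights = sp$weights)
    lnl[b] <- likelihoodFromData(dat, jc, scale = meanRate[b])
    ages_b <- nodeAges(tr)
    for (ci in seq_along(clades))
      cladeAges[b, ci] <- mrcaAge(tr, ages_b, clades[[ci]])
  }
  stats <- data.frame(posterior = lnl, likelihood = lnl)
  samples <- cbind(stats, meanRate = meanRate, as.data.frame(cladeAges))
  list(ensemble = treeEnsemble(trees, stats),
       trace = traceLog(seq_len(ensemble_size), samples))
}
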