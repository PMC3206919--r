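## Synthetic-data generators with known ground truth: Yule trees,
## uncorrelated-lognormal branch rates, forward sequence simulation and
## lognormal node-age samples. One global seed fans out to per-component
## child seeds by fixed offsets so subsystems are independently
## reproducible.

childSeed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Simulation configuration
#'
#' Bundles the study conditions for a full synthetic data set: a
#' calibrated Yule tree, an uncorrelated-lognormal (UCLN) relaxed clock,
#' and per-gene alignments. Defaults emulate a small interspecific
#' mitogenome study: 12 taxa, 10 My root age, clock mean 5e-3
#' substitutions/site/My and 8 coding genes of 600 sites.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param birth_rate Yule birth rate (1/My); the tree is rescaled to
#'   `root_age`, so this only shapes relative node depths.
#' @param root_age root age in My.
#' @param clock_mean mean branch rate, substitutions/site/My.
#' @param clock_cov coefficient of variation of branch rates (0 = strict
#'   clock).
#' @param gene_specs data.frame with columns `name`, `length`, `kind`
#'   (model), `rel_rate` (gene-specific rate multiplier).
#' @param ensemble_size posterior-ensemble size for the emulator.
#' @param seed global seed (mandatory).
#' @return list of class-free config values.
#' @export
simConfig <- function(n_taxa = 12L, birth_rate = 1, root_age = 10,
                      clock_mean = 5e-3, clock_cov = 0.3,
                      gene_specs = defaultGeneSpecs(),
                      ensemble_size = 500L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_taxa >= 3L, birth_rate > 0, root_age > 0, clock_mean > 0,
            clock_cov >= 0, ensemble_size >= 1L)
  list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
       root_age = root_age, clock_mean = clock_mean,
       clock_cov = clock_cov, gene_specs = gene_specs,
       ensemble_size = as.integer(ensemble_size),
       seed = as.integer(seed))
}

#' @rdname simConfig
#' @export
defaultGeneSpecs <- function() {
  data.frame(
    name = paste0("gene", 1:8),
    length = rep(600L, 8),
    kind = c("HKY", "HKY", "HKY", "JC69", "HKY", "K80", "HKY", "HKY"),
    rel_rate = c(1.0, 0.8, 1.2, 0.6, 1.5, 0.9, 1.1, 0.7),
    stringsAsFactors = FALSE)
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree conditioned on the number of taxa (ape's constant-rate
#' birth-death sampler with death rate 0), rescaled so the root age
#' equals `root_age` exactly.
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate birth rate (1/My).
#' @param root_age root age (My).
#' @param seed RNG seed.
#' @return rooted ultrametric `phylo` with tips `t1..tn`.
#' @export
simulateYule <- function(n_taxa, birth_rate = 1, root_age = 1, seed) {
  stopifnot(n_taxa >= 3L)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  tr
}

#' Assign uncorrelated-lognormal branch rates
#'
#' Draws one iid lognormal rate per branch, parameterized so the
#' real-space mean equals `clock_mean` and sd/mean equals `clock_cov`
#' (`clock_cov = 0` degenerates to the strict clock). Rates are attached
#' as `tree$branch.rates`, aligned with the edge matrix.
#'
#' @param tree a `phylo`.
#' @param clock_mean mean rate (substitutions/site/My).
#' @param clock_cov coefficient of variation of rates (>= 0).
#' @param seed RNG seed.
#' @return the tree with a `branch.rates` component.
#' @export
assignUclnRates <- function(tree, clock_mean, clock_cov, seed) {
  stopifnot(clock_mean > 0, clock_cov >= 0)
  nb <- nrow(tree$edge)
  if (clock_cov == 0) {
    tree$branch.rates <- rep(clock_mean, nb)
    return(tree)
  }
  sdlog <- sqrt(log(1 + clock_cov^2))
  meanlog <- log(clock_mean) - sdlog^2 / 2
  set.seed(seed)
  tree$branch.rates <- rlnorm(nb, meanlog, sdlog)
  tree
}

## Sample child states given parent states under transition matrix P.
evolveStates <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in 1:4) {
    idx <- which(parent_states == s)
    if (length(idx))
      out[idx] <- sample.int(4, length(idx), replace = TRUE,
                             prob = P[s, ])
  }
  out
}

#' Forward-simulate an alignment on a tree
#'
#' Root states are drawn from the model's base frequencies and evolved
#' along each branch with expected substitutions/site equal to branch
#' length (time) x branch rate x per-site rate. Per-site rates come from
#' the model's discrete-gamma categories and invariant-site proportion,
#' matching the likelihood engine's mixture.
#'
#' @param tree a `phylo`; if it carries `branch.rates` these multiply
#'   the branch lengths, otherwise rates are 1 (branch lengths already in
#'   substitutions/site).
#' @param model a [SubstModel-class].
#' @param length number of sites.
#' @param seed RNG seed.
#' @return a [MitoAlignment-class] over the tree's tips.
#' @export
simulateAlignment <- function(tree, model, length, seed) {
  stopifnot(length >= 1L)
  set.seed(seed)
  rates <- if (!is.null(tree$branch.rates)) tree$branch.rates
           else rep(1, nrow(tree$edge))
  sublen <- tree$edge.length * rates
  f <- model@baseFreqs
  eig <- eigenQ(rateMatrix(model), f)
  mix <- rateMixture(model)
  ## one rate category per site
  cat_rates <- c(mix$rates, if (mix$pInv > 0) 0)
  cat_w <- c(mix$weights, if (mix$pInv > 0) mix$pInv)
  site_cat <- sample.int(length(cat_rates), length, replace = TRUE,
                         prob = cat_w)
  ntip <- base::length(tree$tip.label)
  states <- matrix(0L, ntip + tree$Nnode, length)
  root <- ntip + 1L
  states[root, ] <- sample.int(4, length, replace = TRUE, prob = f)
  ord <- rev(ape::postorder(tree))  # preorder: parents before children
  for (ei in ord) {
    par <- tree$edge[ei, 1L]; chl <- tree$edge[ei, 2L]
    for (ci in unique(site_cat)) {
      sites <- which(site_cat == ci)
      r <- cat_rates[ci]
      P <- if (r == 0 || sublen[ei] == 0) diag(4)
           else transitionProb(eig, sublen[ei] * r)
      states[chl, sites] <- evolveStates(states[par, sites], P)
    }
  }
  m <- matrix(ACGT[states[seq_len(ntip), , drop = FALSE]], ntip, length)
  rownames(m) <- tree$tip.label
  new("MitoAlignment", seqs = m)
}

#' Lognormal node-age samples with a planted log-scale shift
#'
#' Draws `n` samples from LogNormal(mu + delta, sigma): the ground-truth
#' generator for the TMRCA bias statistic, whose expected value is
#' \eqn{\Phi(\delta/\sigma)} against a target fitted at (mu, sigma).
#'
#' @param mu target log-mean (log-My).
#' @param sigma target log-sd (> 0).
#' @param delta planted log-scale shift.
#' @param n number of draws (>= 100).
#' @param seed RNG seed.
#' @return numeric vector of ages (My).
#' @export
simulateTmrca <- function(mu, sigma, delta = 0, n = 10000L, seed) {
  stopifnot(sigma > 0, n >= 100L)
  set.seed(seed)
  rlnorm(n, mu + delta, sigma)
}
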