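---
title: "Evaluating mitogenome partitions: models, statistics and design choices"
author: "mitopart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating mitogenome partitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopart)
```

## The problem

The mitochondrial genome does not recombine, so its ~16 kb and ~15
conventional partitions (13 protein-coding genes, the combined
12S/16S rRNAs, the control region) share one genealogy. Whole-mitogenome
analyses therefore set the reference: the best-resolved topology, the
tightest node-age posteriors, the most clock-like behaviour. Single
genes are imperfect subsamples of that signal, and this package
quantifies exactly how imperfect — which clades each gene supports,
how far its topology strays, how biased its dates are — and identifies
the smallest gene subset that restores mitogenome-level results.

The package consumes multiple sequence alignments with gene
annotations, posterior tree ensembles and MCMC trace logs. The Bayesian
tree inference that produces such ensembles is deliberately out of
scope: ensembles are inputs, or are emulated by the synthetic-data
module with known ground truth.

## Cutting partitions

Coordinates are 1-based and inclusive, with `end < start` wrapping the
circular origin, matching the convention of mtDNA feature tables. Genes
annotated on the minus strand are reverse-complemented on extraction so
their codon positions read 5'→3' — required for codon partitioning
(vertebrate mtDNA has one such gene, ND6). Overlapping genes (mtDNA
overlaps run to ~16 nt) keep their shared columns in *both* partitions;
nothing is deduplicated, so in a genes × codon-positions scheme every
overlap-shared site is counted once per gene containing it.

Haplotype counting treats sequences as equal only when their full
strings match exactly: a gap or `N` difference founds a new haplotype.
The alternative (ignoring ambiguous sites) is defensible but
unimplemented; exact equality is reproducible and errs toward counting
more haplotypes.

## Distances and saturation

Raw p-distances use pairwise deletion: a site enters a pair's
comparison only when both sequences carry an unambiguous base. The JC69
correction is $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; at
$p \ge 0.75$ the formula is singular and the pair is *flagged*
saturated rather than raising an error, because saturation is itself a
result — the saturation table (raw vs corrected per pair) is meant to
be plotted to diagnose multiple hits, and we leave any axis
standardization to the caller. Neighbor-Joining is the standard
Saitou–Nei agglomeration (via ape), with negative branch-length
estimates clamped to zero.

## Tree ensembles

Posterior samples keep file order so burn-in has meaning; the default
burn-in is 10% everywhere. Clade support is *rooted* monophyly
frequency, and PP > 0.6 (strict) is the minimum support threshold used
by the selection algorithm. The PH85 topology distance uses unrooted
non-trivial bipartitions, per its published definition; mixing rooted
support with unrooted distances mirrors how these statistics are used
in practice. Polytomies are accepted on input and simply contribute
fewer bipartitions.

The MCC tree is the *sampled* tree maximizing the product of its
clades' posterior frequencies (never a consensus: consensus trees hide
low resolution inside polytomies, whereas a best sampled tree lets weak
genes be compared by PP). Ties are broken by earliest sample index.
Node heights are re-annotated with per-clade median heights across all
samples containing the clade; medians of different clades need not be
monotone, so a root-to-tip pass clamps children below parents.

Credible sets are defined on the per-sample posterior scalar: the
samples whose posterior log density lies in the HPD interval of that
scalar at the chosen level. (Keying on cumulative topology frequencies
is a reasonable alternative; we follow the scalar definition and do
not second-guess it.) A reference topology is "contained" when some
retained sample has PH85 distance zero to it.

## Likelihoods and model selection

The pruning engine supports the GTR family (JC69, K80 and HKY as
special cases), discrete-gamma rate variation with four
equal-probability categories summarized by their *means*, and a
proportion of invariant sites; rate matrices are scaled to mean rate 1
so branch lengths are expected substitutions per site, and with +I the
variable-site rates are rescaled by $1/(1-p_{inv})$ so the overall
mean stays 1. Gaps and ambiguity codes contribute a partial likelihood
of 1 over their compatible states. The engine agrees with an
independent implementation (phangorn's) to ~1e-6 on shared models; the
tests keep that cross-check.

Model fitting optimizes the substitution parameters plus a *single*
branch-length multiplier on a fixed guide tree (NJ on JC69 distances by
default) — per-branch optimization buys little for model *ranking* and
costs much. Optimization is bounded quasi-Newton (L-BFGS-B) on
log/logit-transformed parameters with three spread restarts. Kappa is
capped at 1e4: data with essentially no observed transversions push the
transition/transversion ratio to infinity, and the binding cap is
reported as a `kappa-at-bound` warning instead of a spurious estimate.

The candidate space is {JC69, K80, HKY, GTR} × {plain, +I, +G, +I+G}
(16 models) — the models actually selected for mitochondrial data in
this setting all live here, and a larger space adds bulk, not coverage.
BIC is $-2\ln L + k\ln n$ with $n$ = alignment sites by default; some
tools fix an arbitrary $n$ (e.g. 1000) instead, so `n` is exposed as an
override. $k$ counts substitution parameters, estimated frequencies,
shape, $p_{inv}$ and the branch multiplier.

## Trace statistics and date estimation

ESS uses $N/(1+2\sum_k \rho_k)$ with the autocorrelation sum truncated
at the first non-positive estimate — the simplest defensible rule, and
the one easiest to reason about in tests. HPD intervals are the
shortest contiguous run of sorted samples containing
$\lceil\text{level}\cdot N\rceil$ points, so endpoints are always
sample values. The coefficient of rate variation is the plain sample
sd/mean of branch rates (unweighted; some samplers weight by branch
duration, but the verbal definition is unweighted and that is what we
implement).

The bias statistic: log-transform the reference partition's node-age
samples and fit a normal by moments (this *is* the lognormal MLE),
giving the target $(\mu, \sigma)$; for each observed age $x$ compute
$q = \Phi((\ln x - \mu)/\sigma)$; the bias is the proportion of
observations with $q$ strictly $> 0.5$ (a $q$ of exactly 0.5 counts as
not-over, for determinism). Natural logs throughout — the base cancels
in $q$ but not in the reported $\mu,\sigma$. For observations drawn
from LogNormal$(\mu+\delta, \sigma_o)$ the statistic converges to
$\Phi(\delta/\sigma_o)$: it measures the *shift* in units of the
observed spread, which equals $\Phi(\delta/\sigma)$ in the usual regime
$\sigma_o \approx \sigma$ where observed and target posteriors have
similar widths.

The ANOVA on log TMRCA treats MCMC draws as independent observations.
That is pseudo-replication — with thousands of draws per group even
trivial differences are "significant" — and the result carries a note
saying so; we report the conventional computation rather than silently
"fixing" it.

Calibration cross-validation: remove one fossil calibration, re-run,
and ask how much of the removed prior's mass the posterior recovers.
We operationalize "overlap" as the integral of the (offset-shifted)
lognormal prior density over the posterior's 95% HPD interval, which is
1 exactly when the prior sits wholly inside the interval; a boolean
companion (`priorContained`) reports whether the prior's central 95%
mass lies within the posterior's 95% HPD.

## Marginal likelihoods and partitioning schemes

Scheme comparison (1 partition / 3 codon positions / one per gene /
gene × codon) uses the harmonic-mean estimator of the log marginal
likelihood, $\ln N - \mathrm{logsumexp}(-\ell_i)$, computed in log
space so traces near $-2\times10^4$ cannot overflow. The estimator's
upward instability — it flatters parameter-rich models — is documented
in the output note and *not* corrected, because the comparison being
reproduced used it as-is; path sampling and stepping-stone are better
and deliberately out of scope. Standard errors come from 1000 bootstrap
resamples of the post-burn-in trace (seeded). Burn-in removal is the
caller's responsibility, once — the functions do not remove it again.

## Informative-gene selection

Given the genes × clades PP matrix: (1) every gene that is the *sole*
supporter of some clade is selected; (2) remaining uncovered clades are
covered greedily by the gene adding the most of them, with ties broken
by higher PP on the tied clades, then by lower CoV, then
lexicographically. The exact tie-break used historically is not
documented anywhere we could follow, so ours is a stated
reconstruction; on the shipped killer-whale support values it selects
COX1, ND3, CYTB and ATP6, with ATP6 chosen over equally-supporting
rivals precisely because of its lower rate-variation coefficient.
Greedy set cover is approximate — no minimality claim is made, and the
report records coverage, the greedy order and the tie-break used at
each step. A final validation checks that the concatenated subset's
ensemble supports every clade above the threshold.

## The synthetic-data generator

Defaults emulate a small interspecific mitogenome study: 12 taxa, a
10 My Yule chronogram, UCLN clock with mean 5×10⁻³ substitutions/
site/My (the magnitude estimated for cetacean mitogenomes) and CoV 0.3,
eight coding genes of 600 sites with gene-specific relative rates
(0.6–1.5×) under HKY/K80/JC69 models, and ensembles of 500 samples.
Yule trees come from ape's constant-rate birth-death sampler
conditioned on the tip count, rescaled so the root age is exact. UCLN
rates are iid lognormal parameterized by real-space mean and CoV, so
the generator's `clock_cov` plugs directly into `rateCov` recovery
tests.

Posterior ensembles are *emulated*, not MCMC-sampled: topologies come
from a nonparametric bootstrap of alignment columns followed by NJ on
JC69 distances and midpoint rooting, so clade frequencies track signal
strength (long alignments concentrate, 100-site alignments lose
resolution); each sample is made ultrametric by jittering the true
tree's node ages lognormally (log-sd `age_log_sd`). A bootstrap clade
absent from the true tree takes the jittered age of the true tree's
MRCA of its taxa — monotone by construction, with a root-to-tip clamp
as backstop. The trace log carries the data's JC69 log-likelihood on
each sampled tree (serving as the posterior scalar), a mean-rate
column, and per-clade MRCA ages. What this emulation does *not*
reproduce: tree priors, hastings ratios, autocorrelated chains (each
sample is independent, so ESS ≈ N), or model misspecification effects.
Passing tests therefore show the *statistics* behave correctly on
ensembles with known properties — not that any particular real
posterior is well calibrated.

One global seed fans out to per-component child seeds by fixed offsets,
so the tree, the rates, each gene's alignment and each partition's
ensemble are independently reproducible.

## Numerical choices and degenerate inputs

* Zero-variance traces: ESS reports $N$ with a warning; the HPD of a
  constant sample is the point interval.
* A degenerate target fit ($\sigma = 0$) computes bias as the fraction
  of log-ages above $\mu$, with a warning.
* Saturated JC69 pairs propagate as flags in saturation tables, as
  errors into NJ (which cannot use them), and as a per-pair fallback to
  raw distances inside the posterior emulator.
* Empirical base frequencies carry a half-count pseudo-count so a base
  absent from a short alignment cannot zero the likelihood.
* Pattern compression makes the likelihood linear in *distinct* site
  columns; duplicating an alignment exactly doubles its log-likelihood
  (tested).

## Problem sizes

The shipped tests run the statistics at n = 10,000–20,000 draws,
model fitting at 2,000–5,000 sites on 8-taxon trees, PH85 verification
on 200 random 6–8 taxon tree pairs, and one full synthetic study at the
default 12 × 8 × 600 size — chosen as the smallest scales at which the
stochastic recoveries (CoV, kappa, bias, clade support) sit comfortably
inside their sampling error.

## Known limitations

* The emulator's posterior scalar is a likelihood, not a posterior
  density; credible-set machinery works identically either way.
* The harmonic-mean estimator is reported as-is, instability included.
* No K2P/TN93 distances, no codon or amino-acid models, no per-branch
  optimization, no consensus trees, no Gelman–Rubin diagnostic, no
  de novo alignment — all deliberate non-goals.
* Haplotype counting is exact-string; alignments with heavy missing
  data will over-split haplotypes relative to an ignore-N rule.
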