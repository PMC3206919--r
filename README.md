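# mitopart

Partition evaluation for mitogenome phylogenetics.

Complete mitochondrial genomes usually give better-resolved phylogenies
and more precise divergence dates than any single gene, yet most studies
still sequence one or a few markers. Because the mitogenome is
non-recombining, every gene estimates the *same* genealogy — so the
interesting question is which genes (or small subsets of genes)
reproduce the whole-mitogenome estimate, and by how much the others
mislead. `mitopart` implements that evaluation as a reusable, tested
pipeline for systematists comparing mitochondrial partitions: single
genes, concatenated subsets and codon-position schemes.

## What it computes

Given per-partition posterior tree ensembles and MCMC trace logs (or the
package's own synthetic emulations of them), `mitopart` quantifies:

* **Topology and support.** Clade posterior probabilities
  (PP = fraction of post-burn-in samples in which the clade is
  monophyletic; PP > 0.6 counts as support), maximum-clade-credibility
  (MCC) trees with common-ancestor median node heights, PH85 topology
  distances (the size of the symmetric difference of two trees'
  non-trivial bipartition sets), an NJ dendrogram of gene-tree
  distances, and whether a reference topology is contained in a
  partition's 95% credible set of trees.
* **Informative-gene selection.** The two-step set-cover over a
  genes × clades PP matrix: keep every gene that is the sole supporter
  of some clade, then greedily add the gene covering the most
  still-unsupported clades, breaking ties by clade PP, then by lower
  coefficient of rate variation (CoV = sd/mean of branch rates), then by
  name; finally validate that the concatenated subset supports every
  clade.
* **Date estimation.** ESS (initial-positive-sequence truncation), HPD
  intervals, rate summaries, one-way ANOVA on log TMRCA samples, and a
  TMRCA **bias statistic**: fit a lognormal target (μ, σ) to the
  reference partition's node ages, compute for each observed age
  q = Φ((ln x − μ)/σ), and report the proportion of observations with
  q > 0.5. Bias 0.5 means no bias, above 0.5 overestimation, below 0.5
  underestimation.
* **Calibration cross-validation.** After removing a lognormal
  calibration prior and re-estimating, the proportion of the removed
  prior's mass inside the posterior's 95% HPD (1 = fully recovered by
  the remaining calibrations).
* **Model and scheme choice.** A Felsenstein-pruning likelihood engine
  for JC69/K80/HKY/GTR (+I, +G) with BIC selection over the 16-model
  space, and harmonic-mean log marginal likelihoods with bootstrap
  standard errors and log Bayes factors between partitioning schemes
  (1 / 3 / k / 3k partitions).
* **Synthetic ground truth.** Yule chronograms with calibrated root
  ages, uncorrelated-lognormal (UCLN) branch rates, forward sequence
  simulation, emulated posterior ensembles with controllable clade
  support, and node-age samples with a planted log-scale shift δ whose
  expected bias is Φ(δ/σ).

## Worked example: selecting informative genes

The package ships the published killer-whale clade-support values
(genes × clades PPs with per-gene CoV) as a fixture:

```r
library(mitopart)
m <- readSupportMatrix(system.file("extdata",
                                   "orcinus_clade_support.csv",
                                   package = "mitopart"))
rep <- selectInformative(m, threshold = 0.6)
rep$unique_supporters
#>     AntC Offshore
#>    "ND3"   "COX1"
rep$greedy_order
#>   gene n_new new_clades tiebreak
#> 1 CYTB     1   Atlantic      cov
#> 2 ATP6     1   Resident      cov
rep$selected
#> [1] "ND3"  "COX1" "CYTB" "ATP6"
```

Step 1 keeps ND3 and COX1 because each is the *only* gene supporting a
clade (the Antarctic type C and Offshore ecotypes). Step 2 first adds
CYTB — several genes can each cover one remaining clade at PP 0.99, and
CYTB has by far the lowest rate-variation coefficient (0.73) — which
covers the Atlantic clade; the same CoV tie-break then picks ATP6
(CoV 5.27, vs 5.58/6.41 for its rivals) for the Residents. Four genes,
about a fifth of the mitogenome, cover every clade.

Other statistics print equally directly:

```r
tmrcaBias(simulateTmrca(1.2, 0.35, delta = 0.35, n = 10000, seed = 7),
          c(mu = 1.2, sigma = 0.35))
#> [1] 0.8399          # a +1 sigma shift gives bias ~ Phi(1) = 0.841
jc69Distance(0.1)
#> [1] 0.1073256
harmonicMeanLnL(c(-10, -12))
#> [1] -11.43378
```

A full synthetic study — simulate, partition, support matrix, topology
comparison, dates, cross-validation, scheme comparison — runs in a few
minutes at its default size (12 taxa, 8 genes × 600 sites, ensembles of
500):

```r
cfg <- simConfig(seed = 1L)
runSimulateStudy(cfg, "study")
stage <- list(study_dir = "study", out_dir = "out",
              partitions = c(cfg$gene_specs$name, "concat"),
              schemes = c(cfg$gene_specs$name, "concat"),
              burnin = 0.1, threshold = 0.6, hpd = 0.95,
              reps = 1000L, seed = 1L)
runPartition(stage); runSupportMatrix(stage)
runCompareTopologies(stage); runDates(stage); runPartitionCompare(stage)
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "mitopart.R", package = "mitopart")`.

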