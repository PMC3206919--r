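## Orchestration of the full partition-evaluation analysis over a config
## file: simulate a synthetic study folder, cut partitions, build the
## support matrix, compare topologies, score date estimation, cross-
## validate calibrations and compare partitioning schemes. Each stage
## writes CSV/Newick outputs and returns its tables invisibly.

#' Read a run configuration
#'
#' YAML key-value file. Defaults: `burnin: 0.10`, `threshold: 0.6`,
#' `hpd: 0.95`, `reps: 1000`. Paths are resolved relative to the config
#' file's directory.
#'
#' @param path YAML file.
#' @return named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  defaults <- list(burnin = 0.10, threshold = 0.6, hpd = 0.95,
                   reps = 1000L, seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in grep("(_dir|_file|dir$)", names(cfg), value = TRUE))
    if (is.character(cfg[[nm]]) && !startsWith(cfg[[nm]], "/"))
      cfg[[nm]] <- file.path(base, cfg[[nm]])
  cfg
}

stageLog <- function(stage, t0) {
  message(sprintf("[mitopart] %s: %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Generate a synthetic study folder
#'
#' Writes everything the pipeline consumes, with known ground truth:
#' the true chronogram (`true_tree.nwk`), per-gene and concatenated
#' alignments (FASTA), the gene annotation table, and per-partition
#' emulated posterior ensembles (newick lists) and trace logs.
#'
#' @param config a [simConfig()] list.
#' @param dir output directory (created).
#' @param partitions character; which partitions get ensembles:
#'   defaults to every gene plus `"concat"`.
#' @return invisibly, a list with the true tree and file index.
#' @export
runSimulateStudy <- function(config, dir,
                             partitions = c(config$gene_specs$name,
                                            "concat")) {
  t0 <- as.numeric(Sys.time())
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- simulateYule(config$n_taxa, config$birth_rate, config$root_age,
                     childSeed(config$seed, 1L))
  tr <- assignUclnRates(tr, config$clock_mean, config$clock_cov,
                        childSeed(config$seed, 2L))
  ape::write.tree(tr, file.path(dir, "true_tree.nwk"))
  writeLines(paste(format(tr$branch.rates, digits = 10), collapse = "\t"),
             file.path(dir, "branch_rates.tsv"))
  gs <- config$gene_specs
  parts <- list()
  for (i in seq_len(nrow(gs))) {
    model <- substModel(gs$kind[i],
                        kappa = 4,
                        baseFreqs = c(0.31, 0.25, 0.14, 0.30))
    gtree <- tr
    gtree$branch.rates <- tr$branch.rates * gs$rel_rate[i]
    aln <- simulateAlignment(gtree, model, gs$length[i],
                             childSeed(config$seed, 100L + i))
    parts[[gs$name[i]]] <- aln
    writeAlignment(aln, file.path(dir, paste0(gs$name[i], ".fasta")))
  }
  cc <- concatenateGenes(parts, names(parts), "genes")
  writeAlignment(cc$alignment, file.path(dir, "concat.fasta"))
  ends <- cumsum(gs$length)
  ann <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i)
    geneAnnotation(gs$name[i], ends[i] - gs$length[i] + 1L, ends[i])))
  writeGeneAnnotations(ann, file.path(dir, "annotations.tsv"))
  kk <- cladeKeys(tr)
  clades <- lapply(strsplit(kk$key, "|", fixed = TRUE), identity)
  names(clades) <- paste0("clade", kk$node)
  writeLines(vapply(names(clades), function(nm)
    paste0(nm, ",", paste(clades[[nm]], collapse = ";")), ""),
    file.path(dir, "clades.csv"))
  alns <- c(parts, list(concat = cc$alignment))
  for (p in partitions) {
    em <- emulatePosterior(alns[[p]], tr, config$ensemble_size,
                           age_log_sd = 0.1,
                           seed = childSeed(config$seed, 1000L +
                                            match(p, names(alns))),
                           clades = clades,
                           clock_mean = config$clock_mean)
    writeTrees(em$ensemble, file.path(dir, paste0(p, ".trees.nwk")))
    write.csv(ensembleStats(em$ensemble),
              file.path(dir, paste0(p, ".stats.csv")), row.names = FALSE)
    writeTrace(em$trace, file.path(dir, paste0(p, ".log")))
  }
  stageLog("simulate", t0)
  invisible(list(tree = tr, dir = dir, partitions = partitions,
                 clades = clades))
}

## Load one partition's ensemble (+ stats if present), burn-in applied.
loadEnsemble <- function(dir, partition, burnin) {
  e <- readTrees(file.path(dir, paste0(partition, ".trees.nwk")))
  statf <- file.path(dir, paste0(partition, ".stats.csv"))
  if (file.exists(statf))
    e <- treeEnsemble(ensembleTrees(e), read.csv(statf))
  applyBurnin(e, burnin)
}

readCladesFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",")
  setNames(lapply(parts, function(p) strsplit(p[2L], ";")[[1L]]),
           vapply(parts, `[[`, "", 1L))
}

#' Cut gene partitions out of the study alignment
#'
#' Extracts every annotated gene from the concatenated alignment, writes
#' one FASTA per gene, the haplotype summary, and the partition scheme
#' for the requested mode.
#'
#' @param config list with `study_dir`, `out_dir` and optional
#'   `scheme_mode` (default "by_gene_and_codon").
#' @return invisibly, data.frame of haplotype counts per partition.
#' @export
runPartition <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- readGeneAnnotations(file.path(config$study_dir,
                                       "annotations.tsv"))
  aln <- readAlignment(file.path(config$study_dir, "concat.fasta"))
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    g <- extractGene(aln, ann[i, ])
    writeAlignment(g, file.path(config$out_dir,
                                paste0(ann$name[i], ".fasta")))
    h <- collapseHaplotypes(g, ann$name[i])
    rows[[i]] <- data.frame(partition = h$partition_name,
                            n_sequences = h$n_sequences,
                            n_haplotypes = h$n_unique_haplotypes)
  }
  h <- collapseHaplotypes(aln, "concat")
  rows[[length(rows) + 1L]] <-
    data.frame(partition = "concat", n_sequences = h$n_sequences,
               n_haplotypes = h$n_unique_haplotypes)
  hap <- do.call(rbind, rows)
  write.csv(hap, file.path(config$out_dir, "haplotypes.csv"),
            row.names = FALSE)
  mode <- if (is.null(config$scheme_mode)) "by_gene_and_codon"
          else config$scheme_mode
  scheme <- codonPartition(aln, ann, mode)
  writePartitionScheme(scheme,
                       file.path(config$out_dir, "scheme.txt"))
  stageLog("partition", t0)
  invisible(list(haplotypes = hap, scheme = scheme))
}

#' Clade support matrix across partitions
#'
#' Computes the clade posterior probabilities of every named clade in
#' every partition's ensemble (after burn-in), writes the genes x clades
#' CSV (with a CoV column from each trace's `meanRate`), and one MCC
#' tree per partition as Newick.
#'
#' @param config list with `study_dir`, `out_dir`, `partitions`,
#'   `burnin`, `threshold`.
#' @return invisibly, the [SupportMatrix-class].
#' @export
runSupportMatrix <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  clades <- readCladesFile(file.path(config$study_dir, "clades.csv"))
  pp <- matrix(NA_real_, length(config$partitions), length(clades),
               dimnames = list(config$partitions, names(clades)))
  cov <- setNames(numeric(length(config$partitions)), config$partitions)
  for (p in config$partitions) {
    e <- tryCatch(loadEnsemble(config$study_dir, p, config$burnin),
                  error = function(err)
                    stop("partition '", p, "': ",
                         conditionMessage(err)))
    for (cl in names(clades)) pp[p, cl] <- cladePP(e, clades[[cl]])
    mcc <- mccTree(e)
    ape::write.tree(mcc, file.path(config$out_dir,
                                   paste0(p, ".mcc.nwk")))
    tl <- traceBurnin(readTrace(file.path(config$study_dir,
                                          paste0(p, ".log"))),
                      config$burnin)
    cov[p] <- rateCov(traceColumn(tl, "meanRate"))
  }
  m <- supportMatrix(pp, cov)
  writeSupportMatrix(m, file.path(config$out_dir, "support_matrix.csv"))
  stageLog("support-matrix", t0)
  invisible(m)
}

#' Compare partition topologies with the reference
#'
#' Writes the PH85 distance matrix between partition MCC trees plus the
#' reference tree, the NJ dendrogram of those distances, and the 95%
#' credible-set containment report (is the reference topology inside
#' each partition's credible set?).
#'
#' @param config list with `study_dir`, `out_dir`, `partitions`,
#'   `reference` (partition name whose MCC tree is the reference;
#'   default "concat"), `burnin`, `hpd`.
#' @return invisibly, list with `ph85`, `dendrogram`, `containment`.
#' @export
runCompareTopologies <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ref_name <- if (is.null(config$reference)) "concat" else config$reference
  mccs <- list()
  ens <- list()
  for (p in config$partitions) {
    e <- loadEnsemble(config$study_dir, p, config$burnin)
    ens[[p]] <- e
    mccs[[p]] <- mccTree(e)
  }
  ref <- mccs[[ref_name]]
  d <- ph85Matrix(mccs)
  write.csv(d, file.path(config$out_dir, "ph85_matrix.csv"))
  dend <- if (length(mccs) >= 3L) treeDistanceDendrogram(mccs) else NULL
  if (!is.null(dend))
    ape::write.tree(dend, file.path(config$out_dir, "dendrogram.nwk"))
  cont <- data.frame(
    partition = config$partitions,
    contains_reference = vapply(config$partitions, function(p)
      containsTopology(credibleSet(ens[[p]], config$hpd), ref), TRUE))
  write.csv(cont, file.path(config$out_dir, "containment.csv"),
            row.names = FALSE)
  stageLog("compare-topologies", t0)
  invisible(list(ph85 = d, dendrogram = dend, containment = cont))
}

#' Date-estimation report (median, HPD, bias per node and partition)
#'
#' Fits the lognormal target per node from the reference partition's
#' trace and scores every other partition's bias against it; also
#' summarizes each partition's rate column.
#'
#' @param config list with `study_dir`, `out_dir`, `partitions`,
#'   `reference` (default "concat"), `burnin`; `nodes` optionally
#'   restricts the clade columns scored.
#' @return invisibly, data.frame in Tables 2-3 layout.
#' @export
runDates <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ref_name <- if (is.null(config$reference)) "concat" else config$reference
  traces <- lapply(config$partitions, function(p)
    traceBurnin(readTrace(file.path(config$study_dir,
                                    paste0(p, ".log"))), config$burnin))
  names(traces) <- config$partitions
  nodes <- config$nodes
  if (is.null(nodes))
    nodes <- grep("^clade", traceColumns(traces[[ref_name]]),
                  value = TRUE)
  targets <- lapply(nodes, function(nd)
    fitLogTarget(traceColumn(traces[[ref_name]], nd)))
  names(targets) <- nodes
  rows <- list()
  for (p in config$partitions) for (nd in nodes) {
    x <- traceColumn(traces[[p]], nd)
    iv <- hpdInterval(x, 0.95)
    rate <- summarizeRate(traceColumn(traces[[p]], "meanRate"))
    rows[[paste(p, nd)]] <- data.frame(
      partition = p, node = nd,
      median_tmrca = median(x), hpd_low = iv[1L], hpd_high = iv[2L],
      bias = tmrcaBias(x, targets[[nd]]),
      rate_median = rate$median,
      rate_hpd_low = rate$hpd95[1L], rate_hpd_high = rate$hpd95[2L],
      rate_cov = rateCov(traceColumn(traces[[p]], "meanRate")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, file.path(config$out_dir, "dates.csv"),
            row.names = FALSE)
  anova_rows <- lapply(nodes, function(nd) {
    a <- anovaLogTmrca(lapply(traces, traceColumn, column = nd))
    data.frame(node = nd, F = a$F, df_between = a$df_between,
               df_within = a$df_within, p_value = a$p_value)
  })
  write.csv(do.call(rbind, anova_rows),
            file.path(config$out_dir, "anova.csv"), row.names = FALSE)
  stageLog("dates", t0)
  invisible(out)
}

#' Calibration-removal cross-validation
#'
#' For each calibration prior, measures how much of the removed prior's
#' mass falls inside the corresponding posterior 95% HPD (one row per
#' removed prior).
#'
#' @param config list with `study_dir`, `out_dir`, `partitions` (the
#'   partition whose trace holds the posteriors; first is used),
#'   `burnin`.
#' @param priors data.frame with columns `name`, `meanlog`, `sdlog`,
#'   `offset`, `column` (trace column of the node's posterior ages), or
#'   a CSV path.
#' @return invisibly, the overlap data.frame.
#' @export
runCrossval <- function(config, priors) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(priors)) priors <- read.csv(priors)
  tl <- traceBurnin(readTrace(file.path(config$study_dir,
                                        paste0(config$partitions[1L],
                                               ".log"))), config$burnin)
  rows <- lapply(seq_len(nrow(priors)), function(i) {
    pr <- calibrationPrior(priors$name[i], priors$meanlog[i],
                           priors$sdlog[i],
                           if ("offset" %in% colnames(priors))
                             priors$offset[i] else 0)
    x <- traceColumn(tl, priors$column[i])
    data.frame(prior = pr@name, column = priors$column[i],
               overlap = priorOverlap(x, pr),
               contained = priorContained(x, pr))
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(config$out_dir, "crossval.csv"),
            row.names = FALSE)
  stageLog("crossval", t0)
  invisible(out)
}

#' Compare partitioning schemes by harmonic-mean Bayes factors
#'
#' Estimates each scheme's log marginal likelihood from its likelihood
#' trace (harmonic mean, bootstrap SE) and tabulates lnBF against the
#' best scheme.
#'
#' @param config list with `study_dir`, `out_dir`, `schemes` (partition
#'   names whose traces hold the likelihood columns), `burnin`, `reps`,
#'   `seed`.
#' @return invisibly, the comparison data.frame.
#' @export
runPartitionCompare <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ests <- lapply(seq_along(config$schemes), function(i) {
    p <- config$schemes[i]
    tl <- traceBurnin(readTrace(file.path(config$study_dir,
                                          paste0(p, ".log"))),
                      config$burnin)
    marginalEstimate(traceColumn(tl, "likelihood"),
                     reps = config$reps,
                     seed = childSeed(config$seed, 5000L + i))
  })
  names(ests) <- config$schemes
  ml <- vapply(ests, `[[`, 0, "ln_marginal")
  best <- names(ml)[which.max(ml)]
  out <- data.frame(
    scheme = config$schemes,
    ln_marginal = ml,
    bootstrap_se = vapply(ests, `[[`, 0, "bootstrap_se"),
    reps = config$reps,
    lnBF_vs_best = ml - ml[best])
  rownames(out) <- NULL
  write.csv(out, file.path(config$out_dir, "partition_compare.csv"),
            row.names = FALSE)
  stageLog("partition-compare", t0)
  invisible(out)
}

#' Informative-gene selection over a computed support matrix
#'
#' @param config list with `out_dir` and either `support_matrix` (a
#'   [SupportMatrix-class]) or `support_file` (CSV path), plus
#'   `threshold`.
#' @return invisibly, the selection report.
#' @export
runSelectGenes <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- if (!is.null(config$support_matrix)) config$support_matrix
       else readSupportMatrix(config$support_file)
  rep <- selectInformative(m, config$threshold)
  writeLines(c(paste0("threshold,", rep$threshold),
               paste0("selected,", paste(rep$selected, collapse = ";")),
               paste0("uncovered,", paste(rep$uncovered,
                                          collapse = ";"))),
             file.path(config$out_dir, "selection.csv"))
  if (nrow(rep$greedy_order))
    write.csv(rep$greedy_order,
              file.path(config$out_dir, "greedy_order.csv"),
              row.names = FALSE)
  stageLog("select-genes", t0)
  invisible(rep)
}
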