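## Date-estimation statistics: coefficient of rate variation, the
## lognormal-target TMRCA bias statistic, log-TMRCA ANOVA and the
## calibration-removal overlap cross-validation.

#' Coefficient of rate variation
#'
#' Standard deviation of among-branch substitution rates divided by their
#' mean (sample sd, denominator n - 1). Values near 0 indicate clock-like
#' evolution; values well above 1 indicate rate heterogeneity that makes
#' the data unsuitable for date estimation.
#'
#' @param rates positive numeric vector (branch rates or a trace column).
#' @return sd/mean.
#' @export
rateCov <- function(rates) {
  if (any(rates <= 0)) stop("domain error: nonpositive rate")
  sd(rates) / mean(rates)
}

#' Fit the lognormal target to reference TMRCA samples
#'
#' Log-transforms the reference (whole-mitogenome) node-age samples and
#' fits a normal by moments — the lognormal maximum-likelihood fit —
#' yielding the target mean and sd on the natural-log scale.
#'
#' @param target positive TMRCA samples (My), length >= 20.
#' @return named numeric `c(mu, sigma)` (log-My).
#' @export
fitLogTarget <- function(target) {
  stopifnot(length(target) >= 20L)
  if (any(target <= 0)) stop("domain error: nonpositive TMRCA sample")
  lx <- log(target)
  sigma <- sd(lx)
  if (sigma == 0) warning("degenerate target: zero log-scale spread")
  c(mu = mean(lx), sigma = sigma)
}

#' TMRCA bias statistic
#'
#' For each observed node-age sample x, the probability of lying over the
#' target distribution is \eqn{q = \Phi((\ln x - \mu)/\sigma)}; the bias
#' is the proportion of observations with q strictly > 0.5. A value of
#' 0.5 means no bias, above 0.5 overestimation, below 0.5
#' underestimation relative to the target.
#'
#' @param observed positive TMRCA samples of the gene/partition under
#'   evaluation.
#' @param target_fit named `c(mu, sigma)` from [fitLogTarget()].
#' @return proportion in \[0, 1\].
#' @export
tmrcaBias <- function(observed, target_fit) {
  if (any(observed <= 0)) stop("domain error: nonpositive TMRCA sample")
  mu <- target_fit[["mu"]]
  sigma <- target_fit[["sigma"]]
  lx <- log(observed)
  if (sigma <= 0) {
    warning("degenerate target sd: bias computed as fraction ln x > mu")
    return(mean(lx > mu))
  }
  q <- pnorm((lx - mu) / sigma)
  mean(q > 0.5)
}

#' One-way ANOVA on log-transformed TMRCA estimates
#'
#' Classical one-way F test of differences between partitions' node-age
#' samples after natural-log transformation. The MCMC draws are treated
#' as independent observations, as is conventional for this comparison;
#' the pseudo-replication caveat is recorded in the result.
#'
#' @param groups named list of >= 2 positive TMRCA sample vectors.
#' @return list with `F`, `df_between`, `df_within`, `p_value` and a
#'   `note` on pseudo-replication.
#' @export
anovaLogTmrca <- function(groups) {
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 samples")
  if (any(unlist(groups) <= 0)) stop("domain error: nonpositive TMRCA")
  df <- data.frame(
    y = log(unlist(groups, use.names = FALSE)),
    g = factor(rep(names(groups), lengths(groups))))
  tab <- summary(aov(y ~ g, data = df))[[1L]]
  list(F = tab[["F value"]][1L],
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       p_value = tab[["Pr(>F)"]][1L],
       note = "MCMC draws treated as independent observations")
}

#' Calibration-prior overlap with a posterior
#'
#' After removing a node's calibration prior and re-estimating, this
#' measures how much of the removed prior's probability mass falls inside
#' the posterior's 95% HPD interval: the integral of the (offset)
#' lognormal prior density over that interval. A value of 1 means the
#' prior is fully contained in the posterior (the remaining calibrations
#' recover it); near 0 means prior and posterior disagree.
#'
#' @param posterior node-age posterior samples (length >= 100).
#' @param prior a [CalibrationPrior-class].
#' @param level HPD level (default 0.95).
#' @return proportion in \[0, 1\].
#' @export
priorOverlap <- function(posterior, prior, level = 0.95) {
  stopifnot(length(posterior) >= 100L)
  iv <- hpdInterval(posterior, level)
  lo <- iv[1L] - prior@offset
  hi <- iv[2L] - prior@offset
  if (hi <= 0) {
    warning("prior undefined on the posterior HPD interval")
    return(0)
  }
  lo <- max(lo, 0)
  plnorm(hi, prior@meanlog, prior@sdlog) -
    plnorm(lo, prior@meanlog, prior@sdlog)
}

#' Is the prior's 95% HPD contained in the posterior's?
#'
#' Boolean companion to [priorOverlap()]: TRUE iff the prior's central
#' 95% mass lies within the posterior's 95% HPD interval.
#'
#' @inheritParams priorOverlap
#' @return logical.
#' @export
priorContained <- function(posterior, prior, level = 0.95) {
  iv <- hpdInterval(posterior, level)
  a <- (1 - level) / 2
  plo <- prior@offset + qlnorm(a, prior@meanlog, prior@sdlog)
  phi <- prior@offset + qlnorm(1 - a, prior@meanlog, prior@sdlog)
  plo >= iv[1L] && phi <= iv[2L]
}

#' Percent excess of a median TMRCA over a reference
#'
#' `100 * (observed - reference) / reference`; e.g. a gene's printed
#' median node age against the whole-mitogenome median.
#'
#' @param observed observed median TMRCA.
#' @param reference reference (mitogenome) median TMRCA.
#' @return percentage.
#' @export
percentExcess <- function(observed, reference)
  100 * (observed - reference) / reference
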