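## Harmonic-mean marginal-likelihood estimation, log Bayes factors and
## bootstrap standard errors for comparing partitioning schemes.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Harmonic-mean estimator of the log marginal likelihood
#'
#' \eqn{\ln N - \mathrm{logsumexp}(-\ell_i)} over post-burn-in
#' log-likelihood samples, computed entirely in log space so values of
#' magnitude 1e5 do not overflow. The estimator's known upward
#' instability (it tends to favour models with more parameters) is not
#' corrected.
#'
#' @param loglik numeric log-likelihood samples (length >= 2, burn-in
#'   already removed).
#' @return estimated log marginal likelihood.
#' @export
harmonicMeanLnL <- function(loglik) {
  if (length(loglik) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood input")
  log(length(loglik)) - logSumExp(-loglik)
}

#' Bootstrap standard error of a trace statistic
#'
#' Standard deviation of the statistic over `reps` resamples with
#' replacement of the full vector (seeded).
#'
#' @param samples numeric vector.
#' @param statistic currently `"harmonic_mean"`.
#' @param reps bootstrap replicates (default 1000, minimum 100).
#' @param seed RNG seed.
#' @return standard error.
#' @export
bootstrapSE <- function(samples, statistic = "harmonic_mean", reps = 1000L,
                        seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(reps >= 100L)
  stat <- switch(statistic, harmonic_mean = harmonicMeanLnL)
  n <- length(samples)
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(i)
    stat(samples[sample.int(n, n, replace = TRUE)]), 0)
  sd(vals)
}

#' Marginal-likelihood estimate with bootstrap SE
#'
#' @param loglik log-likelihood trace samples (burn-in removed).
#' @param reps bootstrap replicates (default 1000); `0` skips the SE.
#' @param seed RNG seed for the bootstrap.
#' @return list with `ln_marginal`, `n_samples`, `bootstrap_se`, `reps`
#'   and a `note` about the estimator's upward instability.
#' @export
marginalEstimate <- function(loglik, reps = 1000L, seed = 1L) {
  se <- if (reps > 0) bootstrapSE(loglik, "harmonic_mean", reps, seed)
        else NA_real_
  list(ln_marginal = harmonicMeanLnL(loglik),
       n_samples = length(loglik),
       bootstrap_se = se, reps = as.integer(reps),
       note = "harmonic-mean estimator; tends to favour richer models")
}

#' Natural-log Bayes factor
#'
#' Difference of two log marginal likelihoods; positive values favour the
#' first model/scheme.
#'
#' @param m1,m2 results of [marginalEstimate()] (or bare numbers).
#' @return lnBF (scalar).
#' @export
lnBayesFactor <- function(m1, m2) {
  v1 <- if (is.list(m1)) m1$ln_marginal else m1
  v2 <- if (is.list(m2)) m2$ln_marginal else m2
  if (!is.finite(v1) || !is.finite(v2)) stop("non-finite estimate")
  v1 - v2
}
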