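## MCMC trace-log parsing and sampling diagnostics (ESS, HPD).

#' Read a tab-separated MCMC trace log
#'
#' Tracer/BEAST dialect: `#` comment lines are skipped, the first column
#' is the state counter, remaining columns are numeric parameter samples.
#'
#' @param path file path.
#' @return a [TraceLog-class].
#' @export
readTrace <- function(path) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               colClasses = "numeric", check.names = FALSE),
    error = function(e) stop("parse error in trace log '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) stop("trace log needs a state column plus data")
  traceLog(df[[1L]], df[, -1L, drop = FALSE])
}

#' Write a trace log (tab-separated, Tracer dialect)
#'
#' @param trace a [TraceLog-class].
#' @param path output file.
#' @export
writeTrace <- function(trace, path) {
  df <- cbind(state = trace@state, trace@samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mitopart trace log", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove burn-in rows from a trace log
#'
#' @param trace a [TraceLog-class].
#' @param fraction burn-in fraction in \[0, 1) (default 0.10).
#' @return truncated [TraceLog-class].
#' @export
traceBurnin <- function(trace, fraction = 0.1) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(trace@state)
  drop <- floor(fraction * n)
  if (drop >= n) stop("burn-in error: no samples left")
  keep <- (drop + 1L):n
  traceLog(trace@state[keep], trace@samples[keep, , drop = FALSE])
}

#' Effective sample size
#'
#' \eqn{N / (1 + 2\sum\rho_k)} with autocorrelations summed until the
#' first non-positive estimate (initial-positive-sequence truncation).
#' A zero-variance column reports ESS = N with a warning.
#'
#' @param x numeric sample vector of length >= 10.
#' @return effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  if (var(x) == 0) {
    warning("zero-variance trace: ESS reported as N")
    return(as.numeric(n))
  }
  rho <- as.numeric(acf(x, lag.max = n - 1L, plot = FALSE)$acf)[-1L]
  s <- 0
  for (r in rho) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

## Core HPD computation shared by hpd() and credibleSet().
hpdInterval <- function(x, level) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(level * n)
  if (m >= n) return(c(xs[1L], xs[n]))
  starts <- 1:(n - m + 1L)
  widths <- xs[starts + m - 1L] - xs[starts]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}

#' Highest-posterior-density interval
#'
#' Shortest contiguous interval of sorted samples containing
#' `ceiling(level * N)` points; endpoints are elements of `x`.
#'
#' @param x numeric samples.
#' @param level probability in (0, 1) (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(x) < 20L) stop("need at least 20 samples")
  hpdInterval(x, level)
}

#' Median and 95% HPD of a rate (or any) trace column
#'
#' @param x numeric samples (length >= 20).
#' @return list with `median` and `hpd95 = c(lower, upper)`.
#' @export
summarizeRate <- function(x) {
  stopifnot(length(x) >= 20L)
  list(median = median(x), hpd95 = hpdInterval(x, 0.95))
}
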