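test_that("trace logs parse the Tracer dialect", {
  path <- tempfile(fileext = ".log")
  writeLines(c("# comment line", "# another",
               "state\tposterior\trate",
               paste(seq(0, 9000, by = 1000),
                     round(rnorm(10), 4), round(runif(10), 4),
                     sep = "\t")), path)
  tl <- readTrace(path)
  expect_equal(length(tl@state), 10L)
  expect_setequal(traceColumns(tl), c("posterior", "rate"))
  expect_equal(length(traceColumn(tl, "posterior")), 10L)
  expect_error(traceColumn(tl, "nope"), "no trace column")

  bad <- tempfile(fileext = ".log")
  writeLines(c("state\tx", "0\t1.0", "1000\tabc"), bad)
  expect_error(readTrace(bad), "parse error")
})

test_that("trace logs round-trip through write and read", {
  tl <- traceLog(1:50, data.frame(a = rnorm(50), b = runif(50)))
  path <- tempfile(fileext = ".log")
  writeTrace(tl, path)
  back <- readTrace(path)
  expect_equal(traceColumn(back, "a"), traceColumn(tl, "a"),
               tolerance = 1e-6)
  tb <- traceBurnin(tl, 0.1)
  expect_equal(length(tb@state), 45L)
})

test_that("ESS is ~N for iid draws and shrinks for autocorrelated ones", {
  set.seed(26)
  x <- rnorm(10000)
  expect_gt(ess(x), 8000)
  expect_lt(ess(x), 12000)
  ## AR(1), phi = 0.9: ESS ~ N (1-phi)/(1+phi)
  phi <- 0.9
  ar <- numeric(10000)
  for (i in 2:10000) ar[i] <- phi * ar[i - 1] + rnorm(1)
  expect_equal(ess(ar), 10000 * (1 - phi) / (1 + phi), tolerance = 0.3)
  expect_warning(e0 <- ess(rep(3, 100)), "zero-variance")
  expect_equal(e0, 100)
})

test_that("HPD is the shortest interval with endpoints in the sample", {
  set.seed(27)
  u <- runif(10000)
  iv <- hpd(u, 0.95)
  expect_equal(iv[2] - iv[1], 0.95, tolerance = 0.02)
  expect_true(all(iv %in% u))
  const <- rep(2.5, 30)
  expect_equal(hpd(const, 0.95), c(2.5, 2.5))
  ## HPD is never wider than the equal-tailed interval
  x <- rlnorm(5000, 1, 0.7)
  h <- hpd(x, 0.9)
  q <- quantile(x, c(0.05, 0.95))
  expect_lte(h[2] - h[1], q[2] - q[1] + 1e-12)
})

test_that("rate CoV is sd/mean and scale-invariant", {
  expect_equal(rateCov(rep(2, 10)), 0)
  expect_equal(rateCov(c(1, 1, 1, 3)), 2 / 3, tolerance = 1e-12)
  set.seed(28)
  r <- rlnorm(50, -1, 0.4)
  expect_equal(rateCov(r), rateCov(100 * r))
  expect_error(rateCov(c(1, 0)), "domain error")
  expect_error(rateCov(c(1, -2)), "domain error")
})

test_that("the lognormal target fit recovers moments on the log scale", {
  expect_warning(ft <- fitLogTarget(rep(exp(1), 25)), "degenerate")
  expect_equal(unname(ft["mu"]), 1)
  set.seed(29)
  x <- rlnorm(50000, 0.5, 0.2)
  ft2 <- fitLogTarget(x)
  expect_equal(unname(ft2["mu"]), 0.5, tolerance = 0.01)
  expect_equal(unname(ft2["sigma"]), 0.2, tolerance = 0.01)
  expect_equal(fitLogTarget(rev(x)), ft2)
  expect_error(fitLogTarget(c(rep(1, 30), -1)), "domain error")
})

test_that("bias is 0.5 under the null and follows Phi(delta/sigma)", {
  target <- c(mu = 0.5, sigma = 0.3)
  obs0 <- simulateTmrca(0.5, 0.3, delta = 0, n = 10000, seed = 30)
  expect_equal(tmrcaBias(obs0, target), 0.5, tolerance = 0.02)
  obs1 <- simulateTmrca(0.5, 0.3, delta = 0.3, n = 10000, seed = 31)
  expect_equal(tmrcaBias(obs1, target), pnorm(1), tolerance = 0.02)
  ## all observations below e^mu
  low <- exp(0.5) * exp(-abs(rnorm(100)) - 0.01)
  expect_equal(tmrcaBias(low, target), 0)
})

test_that("bias recovers Phi(delta/sigma) across planted shifts", {
  sigma <- 0.4
  for (i in seq_along(dd <- c(-2, -1, 0, 1, 2))) {
    obs <- simulateTmrca(1, sigma, delta = dd[i] * sigma,
                         n = 20000, seed = 320 + i)
    expect_lt(abs(tmrcaBias(obs, c(mu = 1, sigma = sigma)) -
                  pnorm(dd[i])), 0.02)
  }
  ## the statistic depends on the observed spread only through the
  ## fraction of log-ages above mu: Phi(delta / sigma_obs)
  obs <- simulateTmrca(1, sigma * 0.5, delta = sigma, n = 20000,
                       seed = 326)
  expect_lt(abs(tmrcaBias(obs, c(mu = 1, sigma = sigma)) - pnorm(2)),
            0.02)
})

test_that("bias is nondecreasing in the planted shift", {
  target <- c(mu = 0, sigma = 0.5)
  vals <- vapply(seq_along(dd <- seq(-1, 1, by = 0.25)), function(i)
    tmrcaBias(simulateTmrca(0, 0.5, dd[i], n = 5000, seed = 340 + i),
              target), 0)
  expect_true(all(diff(vals) >= -0.02))
})

test_that("one-way ANOVA on log ages matches the hand-computed table", {
  ## groups of raw logs {1,2,3} and {2,3,4}: SSB=1.5/df1, SSW=4/df4
  a <- anovaLogTmrca(list(g1 = exp(c(1, 2, 3)), g2 = exp(c(2, 3, 4))))
  expect_equal(a$F, 1.5, tolerance = 1e-10)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)
  expect_equal(a$p_value, pf(1.5, 1, 4, lower.tail = FALSE))
})

test_that("ANOVA separates shifted groups and not identical ones", {
  set.seed(35)
  same <- exp(rnorm(100))
  a0 <- anovaLogTmrca(list(a = same, b = same))
  expect_lt(a0$F, 1e-10)
  expect_gt(a0$p_value, 0.999)
  a1 <- anovaLogTmrca(list(a = exp(rnorm(100)),
                           b = exp(rnorm(100, 5))))
  expect_lt(a1$p_value, 1e-10)
})

test_that("prior overlap integrates the prior over the posterior HPD", {
  set.seed(36)
  ## narrow prior nested in a wide posterior
  post <- rlnorm(10000, 2, 0.6)
  nested <- calibrationPrior("nested", 2, 0.1)
  expect_equal(priorOverlap(post, nested), 1, tolerance = 0.005)
  expect_true(priorContained(post, nested))
  ## disjoint ranges
  far <- calibrationPrior("far", 8, 0.1)
  expect_lt(priorOverlap(post, far), 1e-6)
  expect_false(priorContained(post, far))
  ## prior equal to the generating distribution: ~95% of its own mass
  self <- calibrationPrior("self", 2, 0.6)
  expect_equal(priorOverlap(post, self), 0.95, tolerance = 0.02)
})

test_that("prior overlap is invariant to consistent unit rescaling", {
  set.seed(37)
  post <- rlnorm(5000, 1, 0.4)
  pr <- calibrationPrior("p", 1.2, 0.3)
  ## multiply ages by c: lognormal meanlog shifts by log(c)
  ov1 <- priorOverlap(post, pr)
  ov2 <- priorOverlap(post * 10, calibrationPrior("p", 1.2 + log(10), 0.3))
  expect_equal(ov1, ov2, tolerance = 1e-10)
})

test_that("offset priors shift their support", {
  set.seed(38)
  post <- 5 + rlnorm(5000, 0, 0.2)
  pr <- calibrationPrior("off", 0, 0.2, offset = 5)
  expect_gt(priorOverlap(post, pr), 0.9)
  expect_warning(ov <- priorOverlap(rlnorm(200, -3, 0.05) ,
                                    calibrationPrior("x", 0, 0.2,
                                                     offset = 5)),
                 "undefined")
  expect_equal(ov, 0)
})

test_that("rate summaries report the median inside the 95% HPD", {
  s <- summarizeRate(rep(2.6e-3, 30))
  expect_equal(s$median, 2.6e-3)
  expect_equal(s$hpd95, c(2.6e-3, 2.6e-3))
  set.seed(39)
  x <- rlnorm(20000, log(2.6e-3), 0.25)
  s2 <- summarizeRate(x)
  expect_equal(s2$median, 2.6e-3, tolerance = 0.02)
  expect_gte(s2$median, s2$hpd95[1])
  expect_lte(s2$median, s2$hpd95[2])
})

test_that("percent excess reproduces printed-table arithmetic", {
  expect_equal(percentExcess(12.2, 8.07), 51.18, tolerance = 0.01)
  expect_equal(percentExcess(8, 8), 0)
})
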