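## A balanced ultrametric chronogram whose splits are all deep: easy to
## recover from bootstrap replicates of a long alignment.
deepTree <- function() {
  ape::read.tree(text = paste0(
    "(((A:3,B:3):3,(C:3,D:3):3):4,",
    "((E:3,F:3):3,(G:3,H:3):3):4);"))
}

test_that("Yule trees are ultrametric with the requested root age", {
  tr <- simulateYule(10, birth_rate = 1, root_age = 7.5, seed = 50)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 7.5)
  expect_equal(length(tr$tip.label), 10L)
  t3 <- simulateYule(3, 1, 2, seed = 51)
  expect_equal(t3$Nnode, 2L)  # root plus one internal node
  expect_equal(max(mitopart:::nodeAges(t3)), 2)
  ## determinism
  expect_identical(ape::write.tree(simulateYule(8, 1, 5, seed = 52)),
                   ape::write.tree(simulateYule(8, 1, 5, seed = 52)))
})

test_that("Yule node depths follow pure-birth expectations", {
  ## under the Yule process the expected age of the root is larger than
  ## twice the expected age of the median internal node; check the
  ## ranked mean ages decrease steeply, as pure birth implies
  set.seed(53)
  ages <- t(vapply(1:300, function(i) {
    tr <- simulateYule(8, 1, 1, seed = 530 + i)
    sort(mitopart:::nodeAges(tr)[9:15], decreasing = TRUE)
  }, numeric(7)))
  mean_ranked <- colMeans(ages)
  expect_equal(mean_ranked[1], 1)  # root age pinned by rescaling
  expect_true(all(diff(mean_ranked) < 0))
  ## coalescent-style check: second-oldest node is well below the root
  expect_lt(mean_ranked[2], 0.95)
})

test_that("UCLN rates have the requested mean and spread", {
  tr <- simulateYule(26, 1, 5, seed = 54)  # 50 branches
  strict <- assignUclnRates(tr, 2e-3, 0, seed = 55)
  expect_true(all(strict$branch.rates == 2e-3))
  expect_equal(rateCov(strict$branch.rates), 0)
  relaxed <- assignUclnRates(tr, 2e-3, 0.5, seed = 56)
  expect_equal(length(relaxed$branch.rates), nrow(tr$edge))
  cv <- rateCov(relaxed$branch.rates)
  expect_gt(cv, 0.3)
  expect_lt(cv, 0.7)
  expect_equal(mean(relaxed$branch.rates), 2e-3, tolerance = 0.25)
})

test_that("UCLN rates are independent of branch lengths", {
  set.seed(57)
  cors <- vapply(1:30, function(i) {
    tr <- simulateYule(15, 1, 5, seed = 570 + i)
    tr <- assignUclnRates(tr, 1e-3, 0.5, seed = 870 + i)
    cor(tr$edge.length, tr$branch.rates)
  }, 0)
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("sequence simulation matches JC69 closed-form divergence", {
  ## zero-height tree: identical sequences
  flat <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln0 <- simulateAlignment(flat, substModel("JC69"), 100, seed = 58)
  expect_equal(collapseHaplotypes(aln0)$n_unique_haplotypes, 1L)
  ## p-distance ~ 3/4 (1 - exp(-4d/3)) on a long two-taxon branch
  for (d in c(0.1, 0.5, 1)) {
    t2 <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
    sim <- simulateAlignment(t2, substModel("JC69"), 20000, seed = 59)
    expected <- 0.75 * (1 - exp(-4 * d / 3))
    expect_equal(pDistance(as.matrix(sim)[1, ], as.matrix(sim)[2, ]),
                 expected, tolerance = 0.05)
  }
})

test_that("HKY simulations show the planted transition bias", {
  t2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  tstv <- function(kappa, seed) {
    aln <- simulateAlignment(t2, substModel("HKY", kappa = kappa),
                             20000, seed = seed)
    m <- as.matrix(aln)
    diff <- m[1, ] != m[2, ]
    pair <- paste0(pmin(m[1, diff], m[2, diff]),
                   pmax(m[1, diff], m[2, diff]))
    ts <- sum(pair %in% c("AG", "CT"))
    ts / (sum(diff) - ts)
  }
  expect_gt(tstv(8, 60), 2 * tstv(1, 61))
})

test_that("branch rates modulate the simulated divergence", {
  t2 <- ape::read.tree(text = "(a:10,b:10);")  # time units
  t2$branch.rates <- c(0.005, 0.005)
  sim <- simulateAlignment(t2, substModel("JC69"), 20000, seed = 62)
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_equal(pDistance(as.matrix(sim)[1, ], as.matrix(sim)[2, ]),
               expected, tolerance = 0.05)
})

test_that("emulated posteriors concentrate with signal strength", {
  tr <- deepTree()
  tr <- assignUclnRates(tr, 5e-3, 0, seed = 63)
  m <- substModel("HKY", kappa = 4, baseFreqs = c(.31, .25, .14, .3))
  strong <- simulateAlignment(tr, m, 5000, seed = 64)
  em <- emulatePosterior(strong, tr, ensemble_size = 200, seed = 65)
  kk <- mitopart:::cladeKeys(tr)
  pps <- vapply(kk$key, function(k)
    cladePP(em$ensemble, strsplit(k, "|", fixed = TRUE)[[1]]), 0)
  expect_true(all(pps > 0.95))
  ## 100 sites: resolution loss on at least one true clade
  weak <- simulateAlignment(tr, m, 100, seed = 66)
  emw <- emulatePosterior(weak, tr, ensemble_size = 200, seed = 67)
  ppw <- vapply(kk$key, function(k)
    cladePP(emw$ensemble, strsplit(k, "|", fixed = TRUE)[[1]]), 0)
  expect_true(any(ppw < 0.95))
  ## clade support grows with alignment length
  mid <- simulateAlignment(tr, m, 600, seed = 68)
  emm <- emulatePosterior(mid, tr, ensemble_size = 200, seed = 69)
  ppm <- vapply(kk$key, function(k)
    cladePP(emm$ensemble, strsplit(k, "|", fixed = TRUE)[[1]]), 0)
  expect_gte(mean(ppm), mean(ppw))
  expect_gte(mean(pps), mean(ppm))
})

test_that("emulated ensembles are ultrametric around the true ages", {
  tr <- deepTree()
  tr <- assignUclnRates(tr, 5e-3, 0, seed = 70)
  aln <- simulateAlignment(tr,
                           substModel("HKY", kappa = 4,
                                      baseFreqs = c(.31, .25, .14, .3)),
                           3000, seed = 71)
  em <- emulatePosterior(aln, tr, ensemble_size = 150,
                         age_log_sd = 0.08, seed = 72)
  for (s in ensembleTrees(em$ensemble)[1:10])
    expect_true(ape::is.ultrametric(s, tol = 1e-6))
  ## root-age column scatters around the truth with the planted spread
  root_col <- paste0("clade", length(tr$tip.label) + 1L)
  ages <- traceColumn(em$trace, root_col)
  expect_equal(median(ages), 10, tolerance = 0.05)
  expect_equal(sd(log(ages)), 0.08, tolerance = 0.3)
})

test_that("the emulator's trace round-trips through the Tracer dialect", {
  tr <- deepTree()
  tr <- assignUclnRates(tr, 5e-3, 0, seed = 73)
  aln <- simulateAlignment(tr,
                           substModel("JC69"), 500, seed = 74)
  em <- emulatePosterior(aln, tr, ensemble_size = 120, seed = 75)
  path <- tempfile(fileext = ".log")
  writeTrace(em$trace, path)
  back <- readTrace(path)
  expect_setequal(traceColumns(back), traceColumns(em$trace))
  expect_equal(length(back@state), 120L)
  expect_equal(traceColumn(back, "posterior"),
               traceColumn(em$trace, "posterior"), tolerance = 1e-6)
})

test_that("generators are bit-reproducible for a fixed seed", {
  tr1 <- simulateYule(9, 1, 4, seed = 76)
  tr2 <- simulateYule(9, 1, 4, seed = 76)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  r1 <- assignUclnRates(tr1, 1e-3, 0.4, seed = 77)$branch.rates
  r2 <- assignUclnRates(tr2, 1e-3, 0.4, seed = 77)$branch.rates
  expect_identical(r1, r2)
  a1 <- simulateAlignment(r1 |> (\(r) { t <- tr1; t$branch.rates <- r; t })(),
                          substModel("JC69"), 200, seed = 78)
  a2 <- simulateAlignment(r2 |> (\(r) { t <- tr2; t$branch.rates <- r; t })(),
                          substModel("JC69"), 200, seed = 78)
  expect_identical(as.matrix(a1), as.matrix(a2))
  x1 <- simulateTmrca(1, 0.3, 0.1, 200, seed = 79)
  x2 <- simulateTmrca(1, 0.3, 0.1, 200, seed = 79)
  expect_identical(x1, x2)
})

test_that("planted TMRCA shifts reproduce the bias closed form", {
  target <- c(mu = 2, sigma = 0.25)
  expect_lt(abs(tmrcaBias(simulateTmrca(2, 0.25, 0, 10000, seed = 80),
                          target) - 0.5), 0.02)
  expect_lt(abs(tmrcaBias(simulateTmrca(2, 0.25, 0.25, 10000, seed = 81),
                          target) - pnorm(1)), 0.02)
  expect_lt(tmrcaBias(simulateTmrca(2, 0.25, -0.75, 10000, seed = 82),
                      target), 0.005)
})
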