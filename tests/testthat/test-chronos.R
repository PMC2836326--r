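# Shared desk-scale fixture: a 10-tip chronogram-shaped topology.
chronosFixture <- function() {
  topo <- simulateBDTree(0.15, 0.02, 50, nTarget = 10, seed = 42)
  nTip <- ape::Ntip(topo)
  list(topo = topo, nTip = nTip,
       cons = data.frame(node = nTip + 1L, lower = 8, upper = 30),
       priors = chronosPriors(rttm = 0.15, rttmsd = 0.1, rtrate = 1,
                              rtratesd = 0.5, brownmean = 0.3, brownsd = 0.3))
}

# A reproducible synthetic branch-length dataset under the model's own
# data layer: true ages/rates, expected lengths, MVN noise.
chronosData <- function(fx, seed = 5, noise = 0.08) {
  tr <- fx$topo
  ages <- nodeAges(tr)
  g <- simulateGBMRates(tr, 0.01, 0.002, seed = seed)
  mu <- g$substTree$edge.length
  V <- diag((noise * pmax(mu, 0.005))^2)
  set.seed(seed)
  bhat <- mu + rnorm(length(mu), 0, sqrt(diag(V)))
  list(ages = ages, bhat = bhat, V = V)
}

test_that("root-rate prior derivation is the mean path length over rttm", {
  tr <- ape::read.tree(text = "((a:0.21,b:0.21):0.21,c:0.42);")
  expect_equal(deriveRootRatePrior(tr, 4.2), list(rtrate = 0.1, rtratesd = 0.1))
  tr2 <- ape::read.tree(text = "((a:0.2,b:0.2):0.2,c:0.44);")
  expect_equal(deriveRootRatePrior(tr2, 4.2)$rtrate, mean(c(0.4, 0.4, 0.44)) / 4.2)
  tr3 <- tr; tr3$edge.length <- tr$edge.length * 2
  expect_equal(deriveRootRatePrior(tr3, 4.2)$rtrate, 0.2)
  expect_error(deriveRootRatePrior(ape::unroot(ape::rtree(4)), 4.2), "rooted")
})

test_that("constraints resolve to MRCA nodes and reject non-monophyletic clades", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,(d:2,e:2):1);")
  df <- data.frame(taxa = c("a;b", "d;e", "a;b;c"), lower = c(1, NA, 2),
                   upper = c(5, 4, NA))
  res <- resolveConstraints(tr, df)
  expect_equal(res$node, c(ape::getMRCA(tr, c("a", "b")),
                           ape::getMRCA(tr, c("d", "e")),
                           ape::getMRCA(tr, c("a", "b", "c"))))
  expect_error(resolveConstraints(tr, data.frame(taxa = "a;b;d", lower = 1,
                                                 upper = NA)),
               "non-monophyletic")
  expect_error(resolveConstraints(tr, data.frame(taxa = "a;zz", lower = 1,
                                                 upper = NA)), "not in tree")
})

test_that("an infeasible constraint set is diagnosed before sampling", {
  fx <- chronosFixture()
  tr <- fx$topo
  kid <- tr$edge[tr$edge[, 1] == fx$nTip + 1L, 2]
  kid <- kid[kid > fx$nTip][1]  # an internal child of the root
  cons <- data.frame(node = c(fx$nTip + 1L, kid), lower = c(NA, 50),
                     upper = c(30, NA))  # child older than the root's cap
  dat <- chronosData(fx)
  expect_error(runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), tr,
                             cons, fx$priors,
                             chronosSettings(burnin = 10, samples = 10,
                                             thin = 1), seed = 1),
               "infeasible")
})

test_that("every retained sample honours every calibration bound", {
  fx <- chronosFixture()
  dat <- chronosData(fx)
  post <- runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), fx$topo,
                        fx$cons, fx$priors,
                        chronosSettings(burnin = 300, samples = 300, thin = 1,
                                        negativeLengths = "keep"),
                        seed = 3)
  smp <- ageSamples(post)[, as.character(fx$cons$node)]
  expect_true(all(smp >= fx$cons$lower & smp <= fx$cons$upper))
  # ages respect parent > child throughout: spot-check via the summary tree
  chron <- posteriorChronogram(post, fx$topo)
  expect_true(all(chron$edge.length >= 0))
})

test_that("a degenerate L = U constraint pins the node age exactly", {
  fx <- chronosFixture()
  dat <- chronosData(fx)
  cons <- rbind(fx$cons,
                data.frame(node = fx$nTip + 2L, lower = 12, upper = 12))
  post <- runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), fx$topo,
                        cons, fx$priors,
                        chronosSettings(burnin = 100, samples = 200, thin = 1,
                                        negativeLengths = "keep"),
                        seed = 4)
  expect_true(all(abs(ageSamples(post)[, as.character(fx$nTip + 2L)] - 12) < 1e-9))
})

test_that("chains are deterministic in the seed", {
  fx <- chronosFixture()
  dat <- chronosData(fx)
  s <- chronosSettings(burnin = 50, samples = 50, thin = 1,
                       negativeLengths = "keep")
  p1 <- runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), fx$topo,
                      fx$cons, fx$priors, s, seed = 11)
  p2 <- runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), fx$topo,
                      fx$cons, fx$priors, s, seed = 11)
  expect_identical(ageSamples(p1), ageSamples(p2))
})

test_that("a prior-only run reproduces the gamma root-age prior mean", {
  fx <- chronosFixture()
  edge <- fx$topo$edge
  p0 <- runDatingMCMC(list(lengths = rep(0.1, nrow(edge)),
                           vcov = diag(nrow(edge))),
                      fx$topo, NULL, fx$priors,
                      chronosSettings(burnin = 2000, samples = 6000, thin = 1,
                                      priorOnly = TRUE, rootSlideFrac = 0.5),
                      seed = 2)
  x <- ageSamples(p0)[, 1]
  # heavy autocorrelation: allow a generous Monte-Carlo margin via an
  # effective-sample-size-deflated standard error
  ac <- acf(x, lag.max = 200, plot = FALSE)$acf[-1]
  ess <- length(x) / (1 + 2 * sum(pmax(ac, 0)))
  expect_lt(abs(mean(x) - fx$priors$rttm), 4 * sd(x) / sqrt(ess))
})

test_that("posterior root age responds monotonically to its lower bound", {
  fx <- chronosFixture()
  dat <- chronosData(fx)
  means <- vapply(c(8, 16, 22), function(lb) {
    cons <- data.frame(node = fx$nTip + 1L, lower = lb, upper = 40)
    post <- runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), fx$topo,
                          cons, fx$priors,
                          chronosSettings(burnin = 400, samples = 400, thin = 1,
                                          negativeLengths = "keep"),
                          seed = 6)
    mean(ageSamples(post)[, 1])
  }, numeric(1))
  expect_true(all(diff(means) > -0.5))  # non-decreasing up to MC noise
  expect_gt(means[3], 22)               # hard bound certainly respected
})

test_that("strict-clock data recover true node ages within 10%", {
  fx <- chronosFixture()
  tr <- fx$topo
  ages <- nodeAges(tr)
  mu <- 0.01 * tr$edge.length          # nu = 0: exact clock, rate 0.01
  V <- diag((0.02 * pmax(mu, 0.01))^2) # tight, informative lengths
  cons <- data.frame(node = fx$nTip + 1L,
                     lower = max(ages) * 0.97, upper = max(ages) * 1.03)
  post <- runDatingMCMC(list(lengths = mu, vcov = V), tr, cons, fx$priors,
                        chronosSettings(burnin = 800, samples = 600, thin = 2,
                                        negativeLengths = "keep"),
                        seed = 7)
  s <- ageSummary(post)
  true <- ages[s$node]
  expect_lt(max(abs(s$mean - true) / pmax(true, 1)), 0.1)
})

test_that("the two-step pipeline dates a three-partition alignment end to end", {
  topo <- simulateBDTree(0.12, 0, 40, nTarget = 8, seed = 81)
  g <- simulateGBMRates(topo, 0.004, 0.001, seed = 82)
  models <- list(codon1 = substModel("F84", kappa = 3, alpha = 0.8),
                 codon2 = substModel("F84", kappa = 3, alpha = 0.8),
                 codon3 = substModel("F84", kappa = 5, alpha = 2),
                 rRNA = substModel("F84", kappa = 2, alpha = 0.5))
  aln <- simulateAlignment(g$substTree, models, c(150, 150, 100, 120),
                           seed = 83)
  ages <- nodeAges(topo)
  cons <- data.frame(node = ape::Ntip(topo) + 1L, lower = max(ages) * 0.8,
                     upper = max(ages) * 1.2)
  priors <- chronosPriors(rttm = max(ages) / 100, rttmsd = max(ages) / 100)
  post <- twoStepDate(aln, topo, cons, priors,
                      chronosSettings(burnin = 800, samples = 500, thin = 2),
                      seed = 84, nChains = 2L)
  expect_s4_class(post, "ChronosPosterior")
  expect_false(is.na(post@rhat))
  expect_equal(nrow(ageSamples(post)), 1000)
  # codon3 sites are excluded from dating by construction
  expect_true(all(ageSamples(post)[, 1] >= cons$lower - 1e-9 &
                    ageSamples(post)[, 1] <= cons$upper + 1e-9))
  s <- ageSummary(post)
  true <- ages[s$node]
  expect_lt(median(abs(s$mean - true) / pmax(true, 1)), 0.35)
})

test_that("replicate chains agree on the root age within Monte-Carlo error", {
  fx <- chronosFixture()
  dat <- chronosData(fx)
  s <- chronosSettings(burnin = 1200, samples = 700, thin = 4,
                       negativeLengths = "keep")
  p1 <- runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), fx$topo,
                      fx$cons, fx$priors, s, seed = 21)
  p2 <- runDatingMCMC(list(lengths = dat$bhat, vcov = dat$V), fx$topo,
                      fx$cons, fx$priors, s, seed = 22)
  x1 <- ageSamples(p1)[, 1]; x2 <- ageSamples(p2)[, 1]
  se <- sqrt(var(x1) / 20 + var(x2) / 20)  # conservative ESS of ~20 each
  expect_lt(abs(mean(x1) - mean(x2)), 4 * se)
  expect_lt(splitRhat(x1, x2), 1.25)
})
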