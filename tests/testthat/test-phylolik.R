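test_that("two-taxon closed forms hold at the distance limits", {
  aln <- partitionedAlignment(rbind(t1 = "A", t2 = "A"), "codon1")
  tr0 <- ape::read.tree(text = "(t1:0,t2:0);")
  expect_equal(siteLogLikelihoods(aln, tr0, substModel("GTR")), log(0.25))
  # infinite distance: independence, ln(pi_i * pi_j)
  trInf <- ape::read.tree(text = "(t1:80,t2:80);")
  pi <- c(0.4, 0.3, 0.2, 0.1)
  m <- substModel("GTR", pi = pi)
  alnAC <- partitionedAlignment(rbind(t1 = "A", t2 = "C"), "codon1")
  expect_equal(siteLogLikelihoods(alnAC, trInf, m), log(pi[1] * pi[2]),
               tolerance = 1e-6)
})

test_that("pruning equals brute-force enumeration on random small trees", {
  set.seed(202)
  for (i in 1:12) {
    nTip <- sample(3:5, 1)
    tr <- ape::rtree(nTip)
    model <- randomModel(300 + i)
    mat <- matrix(sample(c("A", "C", "G", "T", "?", "-", "R"), nTip * 6,
                         replace = TRUE, prob = c(rep(1, 4), 0.2, 0.2, 0.2)),
                  nrow = nTip, dimnames = list(tr$tip.label, NULL))
    aln <- partitionedAlignment(mat, rep("codon1", ncol(mat)))
    mine <- siteLogLikelihoods(aln, tr, model)
    oracle <- bruteForceSiteLogLik(mat, tr, model)
    expect_lt(max(abs(mine - oracle)), 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting and row sums are additive", {
  tr <- simulateBDTree(0.1, 0, 25, nTarget = 6, seed = 41)
  g <- simulateGBMRates(tr, 0.01, 0, seed = 42)
  models <- list(codon1 = substModel("GTR", exch = c(1, 4, 1, 1, 4, 1),
                                     alpha = 0.6),
                 rRNA = substModel("GTR", alpha = 2))
  aln <- simulateAlignment(g$substTree, models, c(80, 60), seed = 43)
  base <- siteLogLikelihoods(aln, g$substTree, models)
  rerooted <- ape::root(ape::unroot(g$substTree),
                        outgroup = g$substTree$tip.label[2], resolve.root = TRUE)
  expect_equal(sum(siteLogLikelihoods(aln, rerooted, models)), sum(base),
               tolerance = 1e-8)
  # partition additivity
  p1 <- aln[, sitePartition(aln) == "codon1"]
  p2 <- aln[, sitePartition(aln) == "rRNA"]
  expect_equal(sum(base),
               totalLogLik(p1, g$substTree, models["codon1"]) +
                 totalLogLik(p2, g$substTree, models["rRNA"]),
               tolerance = 1e-10)
  # table rows reproduce totals
  slt <- siteLogLikMatrix(aln, list(a = g$substTree, b = rerooted), models)
  expect_equal(unname(treeLogLik(slt)[1]), sum(base), tolerance = 1e-8)
})

test_that("one gamma category equals the no-variation model", {
  tr <- ape::rtree(5)
  mat <- matrix(sample(c("A", "C", "G", "T"), 5 * 30, replace = TRUE),
                nrow = 5, dimnames = list(tr$tip.label, NULL))
  aln <- partitionedAlignment(mat, rep("rRNA", 30))
  mInf <- substModel("GTR", exch = c(1, 2, 1, 1, 2, 1), alpha = Inf)
  m1 <- substModel("GTR", exch = c(1, 2, 1, 1, 2, 1), alpha = 7,
                   nCategories = 1L)
  expect_equal(siteLogLikelihoods(aln, tr, mInf),
               siteLogLikelihoods(aln, tr, m1), tolerance = 1e-12)
})

test_that("agreement with an independent likelihood implementation", {
  set.seed(77)
  tree <- ape::rtree(6)
  dat <- phangorn::simSeq(tree, l = 150, Q = c(1, 3, 1, 1, 3, 1),
                          bf = c(0.3, 0.25, 0.25, 0.2), type = "DNA")
  aln <- partitionedAlignment(toupper(as.character(dat)), rep("codon1", 150))
  model <- substModel("GTR", exch = c(1, 3, 1, 1, 3, 1),
                      pi = c(0.3, 0.25, 0.25, 0.2), alpha = 0.5)
  fit <- phangorn::pml(tree, dat, bf = c(0.3, 0.25, 0.25, 0.2),
                       Q = c(1, 3, 1, 1, 3, 1), k = 4, shape = 0.5)
  expect_equal(totalLogLik(aln, tree, model), fit$logLik, tolerance = 1e-6)
})

test_that("branch-length optimisation recovers the analytic JC distance", {
  # 2 taxa, 100 sites, 20 differences: t_hat = -3/4 log(1 - 4/3 p)
  mat <- rbind(t1 = rep("A", 100),
               t2 = c(rep("C", 20), rep("A", 80)))
  aln <- partitionedAlignment(mat, rep("codon1", 100))
  tr <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
  fit <- optimizeBranchLengths(aln, tr, substModel("GTR"), tol = 1e-9)
  that <- -0.75 * log(1 - 4 / 3 * 0.2)
  expect_equal(sum(fit$edge.length), that, tolerance = 1e-4)
  expect_true(attr(fit, "converged"))
  # fixed point: restarting at the optimum changes nothing material
  fit2 <- optimizeBranchLengths(aln, fit, substModel("GTR"), tol = 1e-9)
  expect_equal(sum(fit2$edge.length), sum(fit$edge.length), tolerance = 1e-4)
})

test_that("branch lengths are recovered within 10% on long simulated alignments", {
  tr <- simulateBDTree(0.1, 0, 25, nTarget = 5, seed = 51)
  g <- simulateGBMRates(tr, 0.015, 0, seed = 52)
  model <- substModel("GTR", exch = c(1, 3, 1, 1, 3, 1),
                      pi = c(0.3, 0.25, 0.25, 0.2), alpha = 0.8)
  aln <- simulateAlignment(g$substTree, setNames(list(model), "codon1"),
                           6000, seed = 53)
  # compare on the unrooted tree: the two root-adjacent branch lengths are
  # only identifiable through their sum
  truthTree <- ape::unroot(g$substTree)
  start <- truthTree
  start$edge.length <- rep(0.1, nrow(start$edge))
  fit <- optimizeBranchLengths(aln, start, model, tol = 1e-6)
  # each branch within 10% of truth, with an absolute allowance of 0.02
  # subst/site covering sampling noise on near-zero branches
  err <- abs(fit$edge.length - truthTree$edge.length)
  expect_true(all(err < pmax(0.1 * truthTree$edge.length, 0.02)))
  expect_lt(abs(sum(fit$edge.length) - sum(truthTree$edge.length)) /
              sum(truthTree$edge.length), 0.05)
})

test_that("the branch covariance behaves like inverse Fisher information", {
  # 2-taxon JC: var(t_hat) = p(1-p) / (L * (dp/dt)^2), p = 3/4(1 - e^{-4t/3})
  mat <- rbind(t1 = rep("A", 500),
               t2 = c(rep("G", 75), rep("A", 425)))
  aln <- partitionedAlignment(mat, rep("codon1", 500))
  tr <- ape::read.tree(text = "(t1:0.08,t2:0.08);")
  est <- estimateBranchCovariance(aln, tr, substModel("GTR"), tol = 1e-9)
  p <- 0.15
  dpdt <- exp(-4 / 3 * sum(est$lengths))
  analytic <- p * (1 - p) / (500 * dpdt^2)
  # the two root edges are jointly unidentifiable: compare the variance of
  # their sum
  expect_equal(sum(est$vcov), analytic, tolerance = 0.15)
  expect_true(all(diag(est$vcov) >= 0))
})

test_that("branch-length variance shrinks like 1/L", {
  tr <- simulateBDTree(0.1, 0, 25, nTarget = 4, seed = 61)
  g <- simulateGBMRates(tr, 0.02, 0, seed = 62)
  model <- substModel("GTR", alpha = Inf)
  v <- vapply(c(300L, 1200L), function(L) {
    aln <- simulateAlignment(g$substTree, setNames(list(model), "codon1"),
                             L, seed = 63)
    est <- estimateBranchCovariance(aln, g$substTree, model, tol = 1e-7)
    mean(diag(est$vcov))
  }, numeric(1))
  expect_equal(v[1] / v[2], 4, tolerance = 0.5)
})

test_that("NNI search keeps the true topology and improves a perturbed start", {
  tr <- simulateBDTree(0.1, 0, 25, nTarget = 6, seed = 71)
  g <- simulateGBMRates(tr, 0.02, 0, seed = 72)
  model <- substModel("GTR", alpha = Inf)
  aln <- simulateAlignment(g$substTree, setNames(list(model), "codon1"),
                           1000, seed = 73)
  best <- nniSearch(aln, ape::unroot(g$substTree), model, tol = 1e-4)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(best), ape::unroot(tr))), 0)
  # NNI-perturbed start returns home
  wrong <- phangorn::nni(ape::unroot(g$substTree))[[1]]
  wrong$edge.length <- rep(0.05, nrow(wrong$edge))
  found <- nniSearch(aln, wrong, model, tol = 1e-4)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(found), ape::unroot(tr))), 0)
  expect_gte(attr(found, "logLik"), attr(optimizeBranchLengths(
    aln, wrong, model, tol = 1e-4), "logLik"))
})
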