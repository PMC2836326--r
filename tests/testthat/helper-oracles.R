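# Independent oracles used across the suite.  These deliberately avoid the
# package's pruning machinery: transition probabilities come from
# ape::matexpo and likelihoods from explicit enumeration over internal-node
# state assignments.

# Random GTR+Gamma parameterisation.
randomModel <- function(seed, nCategories = sample(c(1L, 4L), 1)) {
  set.seed(seed)
  pi <- runif(4, 0.1, 1); pi <- pi / sum(pi)
  substModel("GTR", exch = runif(6, 0.2, 5), pi = pi,
             alpha = runif(1, 0.2, 3), nCategories = nCategories)
}

# Q matrix normalised to unit mean rate, built independently of the package
# internals (same definition, different code path).
oracleQ <- function(model) {
  pi <- model@pi
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- model@exch
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

# Brute-force per-site log-likelihoods by enumeration over all internal-node
# state assignments, with the gamma mixture averaged explicitly.
bruteForceSiteLogLik <- function(mat, tree, model) {
  Q <- oracleQ(model)
  rates <- discreteGammaRates(model@alpha, model@nCategories)
  nTip <- ape::Ntip(tree)
  nInt <- tree$Nnode
  root <- nTip + 1L
  codes <- list(A = 1L, C = 2L, G = 3L, T = 4L)
  S <- ncol(mat)
  states <- as.matrix(expand.grid(rep(list(1:4), nInt)))
  out <- numeric(S)
  for (s in seq_len(S)) {
    likPerCat <- numeric(length(rates))
    for (ci in seq_along(rates)) {
      P <- lapply(tree$edge.length * model@rate * rates[ci],
                  function(t) ape::matexpo(Q * t))
      tot <- 0
      for (a in seq_len(nrow(states))) {
        assign <- states[a, ]
        p <- model@pi[assign[root - nTip]]
        for (e in seq_len(nrow(tree$edge))) {
          up <- tree$edge[e, 1]; dn <- tree$edge[e, 2]
          si <- assign[up - nTip]
          if (dn <= nTip) {
            ch <- mat[tree$tip.label[dn], s]
            p <- p * if (ch %in% names(codes)) P[[e]][si, codes[[ch]]]
                     else sum(P[[e]][si, .tipCode(ch)])
          } else {
            p <- p * P[[e]][si, assign[dn - nTip]]
          }
        }
        tot <- tot + p
      }
      likPerCat[ci] <- tot
    }
    out[s] <- log(mean(likPerCat))
  }
  out
}

# IUPAC expansion for the oracle (indices of compatible bases).
.tipCode <- function(ch) {
  map <- list(A = 1, C = 2, G = 3, T = 4, R = c(1, 3), Y = c(2, 4),
              S = c(2, 3), W = c(1, 4), K = c(3, 4), M = c(1, 2),
              N = 1:4, "-" = 1:4, "?" = 1:4)
  map[[ch]]
}

# Brute-force Mk1 marginal reconstruction by enumeration; returns
# list(logLik, probs [internal nodes x k]).
bruteForceMk <- function(tree, trait, k, q) {
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
  P <- lapply(tree$edge.length, function(t) ape::matexpo(Q * t))
  nTip <- ape::Ntip(tree)
  nInt <- tree$Nnode
  states <- as.matrix(expand.grid(rep(list(1:k), nInt)))
  lik <- apply(states, 1, function(assign) {
    p <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      up <- tree$edge[e, 1]; dn <- tree$edge[e, 2]
      si <- assign[up - nTip]
      if (dn <= nTip) {
        obs <- trait[[tree$tip.label[dn]]]
        p <- p * if (is.na(obs)) 1 else P[[e]][si, obs + 1L]
      } else p <- p * P[[e]][si, assign[dn - nTip]]
    }
    p
  })
  tot <- sum(lik)
  probs <- t(vapply(seq_len(nInt), function(v)
    vapply(1:k, function(s) sum(lik[states[, v] == s]), numeric(1)) / tot,
    numeric(k)))
  list(logLik = log(tot), probs = probs)
}

# Small fixed alignment fixture on a given tree (simulated, deterministic).
fixtureAlignment <- function(tree, nSites = 120, seed = 1,
                             partition = "codon1") {
  model <- substModel("GTR", exch = c(1, 3, 1, 1, 3, 1),
                      pi = c(0.3, 0.25, 0.25, 0.2), alpha = 0.8)
  models <- setNames(list(model), partition)
  simulateAlignment(tree, models, nSites, seed = seed)
}
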