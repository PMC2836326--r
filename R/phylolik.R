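# Partitioned pruning likelihood engine.
#
# Felsenstein's pruning algorithm over a reversible nucleotide model
# (GTR+Gamma or F84+Gamma), computed per site with per-node rescaling so
# small likelihoods never underflow to -Inf.  Partitions are independent:
# each carries its own model parameters and a branch-length multiplier, and
# the total log-likelihood is the sum over partitions.

# Per-site log-likelihood of one data block (character matrix) on one tree.
.pruneSiteLogLik <- function(mat, tree, model) {
  nTip <- ape::Ntip(tree)
  if (is.null(rownames(mat))) stop("alignment matrix must have taxon rownames")
  if (!setequal(rownames(mat), tree$tip.label))
    stop("alignment taxa and tree tip labels differ")
  tree <- stats::reorder(tree, "postorder")
  S <- ncol(mat)
  nNode <- nTip + tree$Nnode
  eig <- .eigenQ(model)
  rates <- discreteGammaRates(model@alpha, model@nCategories)
  k <- length(rates)
  edge <- tree$edge
  elen <- tree$edge.length * model@rate
  tipPart <- lapply(tree$tip.label, function(tx) .tipPartials(mat[tx, ]))
  names(tipPart) <- NULL
  catLogLik <- matrix(NA_real_, k, S)
  rootNode <- edge[nrow(edge), 1]
  for (ci in seq_len(k)) {
    Pmats <- lapply(elen * rates[ci], function(t) .probMatrix(eig, t))
    part <- vector("list", nNode)
    part[seq_len(nTip)] <- tipPart
    scaler <- numeric(S)
    i <- 1L
    nE <- nrow(edge)
    while (i <= nE) {
      parent <- edge[i, 1]
      acc <- NULL
      while (i <= nE && edge[i, 1] == parent) {
        child <- edge[i, 2]
        contrib <- Pmats[[i]] %*% part[[child]]
        acc <- if (is.null(acc)) contrib else acc * contrib
        i <- i + 1L
      }
      mx <- pmax(acc[1, ], acc[2, ], acc[3, ], acc[4, ])
      pos <- mx > 0
      acc[, pos] <- acc[, pos] / rep(mx[pos], each = 4)
      scaler <- scaler + ifelse(pos, log(mx), -Inf)
      part[[parent]] <- acc
    }
    catLogLik[ci, ] <- log(colSums(model@pi * part[[rootNode]])) + scaler
  }
  if (k == 1L) as.numeric(catLogLik[1, ])
  else apply(catLogLik, 2, .logSumExp) - log(k)
}

#' Per-site log-likelihoods of a tree
#'
#' Runs the pruning algorithm per partition and returns the per-site
#' log-likelihood vector (in alignment site order).  Gap and \code{"?"}
#' symbols contribute a partial-likelihood vector of ones (missing data).
#'
#' @param aln a [PartitionedAlignment-class].
#' @param tree a \code{phylo}; branch lengths in expected substitutions/site.
#'   Rooting is irrelevant for these reversible models.
#' @param models either a single [SubstModel-class] applied to every
#'   partition, or a named list keyed by partition label.
#' @return numeric vector of per-site log-likelihoods; its sum is the tree's
#'   total log-likelihood.
#' @examples
#' aln <- partitionedAlignment(rbind(t1 = c("A", "C"), t2 = c("A", "T")),
#'                             c("codon1", "codon1"))
#' tr <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
#' siteLogLikelihoods(aln, tr, substModel("GTR"))
#' @export
siteLogLikelihoods <- function(aln, tree, models) {
  parts <- unique(sitePartition(aln))
  if (is(models, "SubstModel")) {
    models <- setNames(rep(list(models), length(parts)), parts)
  }
  if (!all(parts %in% names(models)))
    stop("models must cover partitions: ", paste(parts, collapse = ", "))
  out <- numeric(nSites(aln))
  for (p in parts) {
    idx <- which(sitePartition(aln) == p)
    out[idx] <- .pruneSiteLogLik(alnMatrix(aln)[, idx, drop = FALSE], tree,
                                 models[[p]])
  }
  out
}

#' Total log-likelihood of a tree
#'
#' @inheritParams siteLogLikelihoods
#' @return the summed log-likelihood over all sites and partitions.
#' @export
totalLogLik <- function(aln, tree, models) sum(siteLogLikelihoods(aln, tree, models))

#' Per-site log-likelihood table for candidate trees
#'
#' Scores each candidate topology on the same alignment and stacks the
#' per-site vectors into a [SiteLogLikTable-class] for the RELL bootstrap and
#' AU test.
#'
#' @param aln a [PartitionedAlignment-class].
#' @param trees a list of \code{phylo} objects (or \code{multiPhylo}),
#'   optionally named.
#' @param models as in [siteLogLikelihoods()].
#' @return A [SiteLogLikTable-class], one row per tree.
#' @export
siteLogLikMatrix <- function(aln, trees, models) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  nm <- names(trees)
  if (is.null(nm)) nm <- paste0("tree", seq_along(trees))
  scores <- t(vapply(trees, function(tr) siteLogLikelihoods(aln, tr, models),
                     numeric(nSites(aln))))
  rownames(scores) <- nm
  siteLogLikTable(scores)
}

#' Optimise branch lengths by coordinate-wise search
#'
#' Cycles over branches, maximising the total log-likelihood one branch at a
#' time with Brent's method, until a full sweep improves the log-likelihood
#' by less than \code{tol}.  The log-likelihood is non-decreasing across
#' sweeps by construction.
#'
#' @inheritParams siteLogLikelihoods
#' @param tol convergence tolerance in log-likelihood units.
#' @param maxSweeps maximum number of sweeps; if reached, the best tree found
#'   is returned with \code{attr(tree, "converged") = FALSE} and a warning.
#' @param maxLength upper bound for any single branch length.
#' @return the tree with optimised branch lengths; attributes
#'   \code{"logLik"} and \code{"converged"} record the fit.
#' @export
optimizeBranchLengths <- function(aln, tree, models, tol = 1e-6,
                                  maxSweeps = 20L, maxLength = 10) {
  if (any(tree$edge.length < 0)) stop("initial branch lengths must be >= 0")
  cur <- totalLogLik(aln, tree, models)
  converged <- FALSE
  for (sweep in seq_len(maxSweeps)) {
    before <- cur
    for (i in seq_along(tree$edge.length)) {
      f <- function(x) {
        tr2 <- tree
        tr2$edge.length[i] <- x
        totalLogLik(aln, tr2, models)
      }
      opt <- optimize(f, c(0, maxLength), maximum = TRUE,
                      tol = max(tol * 1e-2, 1e-8))
      if (opt$objective > cur) {
        tree$edge.length[i] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("branch-length optimisation stopped at maxSweeps without meeting tol")
  attr(tree, "logLik") <- cur
  attr(tree, "converged") <- converged
  tree
}

#' MLE branch lengths with a curvature-based covariance matrix
#'
#' Optimises branch lengths on a fixed topology, then estimates their
#' covariance as the inverse of the observed Fisher information (numerical
#' Hessian of the negative log-likelihood at the optimum), projected to
#' positive semi-definite if needed.  This mirrors the estbranches step of
#' the two-step dating workflow.
#'
#' @inheritParams optimizeBranchLengths
#' @return list with \code{tree} (optimised), \code{lengths} (edge order of
#'   the tree), \code{vcov}, \code{logLik} and \code{singular} (TRUE if the
#'   Hessian had to be pseudo-inverted).
#' @export
estimateBranchCovariance <- function(aln, tree, models, tol = 1e-6) {
  fit <- optimizeBranchLengths(aln, tree, models, tol = tol)
  b <- fit$edge.length
  nll <- function(x) {
    tr2 <- fit
    tr2$edge.length <- pmax(x, 0)
    -totalLogLik(aln, tr2, models)
  }
  H <- pracma::hessian(nll, b)
  H <- (H + t(H)) / 2
  singular <- FALSE
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) {
    singular <- TRUE
    warning("singular Hessian; using pseudo-inverse for the branch covariance")
    V <- .pinv(H)
  }
  V <- .projectPSD(V)
  list(tree = fit, lengths = b, vcov = V, logLik = attr(fit, "logLik"),
       singular = singular)
}

#' Hill-climbing NNI tree search
#'
#' Starting from a bifurcating tree, repeatedly evaluates all
#' nearest-neighbour-interchange rearrangements (with branch-length
#' re-optimisation) and moves to the best-improving neighbour until no
#' rearrangement improves the log-likelihood.  A desk-scale stand-in for a
#' full ML tree search.
#'
#' @inheritParams optimizeBranchLengths
#' @param initLength branch length used to initialise candidate topologies.
#' @return the best tree found, with attribute \code{"logLik"}.
#' @export
nniSearch <- function(aln, tree, models, tol = 1e-6, initLength = 0.1) {
  if (!ape::is.binary(ape::unroot(tree))) stop("start tree must be bifurcating")
  # distance-based starts (NJ) can carry small negative branch lengths
  tree$edge.length <- pmax(tree$edge.length, 0)
  score <- function(topo) {
    topo$edge.length <- rep(initLength, nrow(topo$edge))
    optimizeBranchLengths(aln, topo, models, tol = tol)
  }
  cur <- optimizeBranchLengths(aln, tree, models, tol = tol)
  repeat {
    nbs <- .asPhyloList(phangorn::nni(ape::unroot(cur)))
    fits <- lapply(nbs, score)
    lnls <- vapply(fits, function(f) attr(f, "logLik"), numeric(1))
    best <- which.max(lnls)
    if (lnls[best] > attr(cur, "logLik") + tol) {
      cur <- fits[[best]]
    } else break
  }
  cur
}

#' Fit substitution-model parameters on a fixed tree
#'
#' Crude but serviceable ML fitting of the gamma shape (and, for F84, kappa)
#' together with branch lengths, by alternating 1-D parameter optimisation
#' and branch-length sweeps.  Base frequencies are set to their empirical
#' values (the usual practice for these models).
#'
#' @inheritParams optimizeBranchLengths
#' @param model a template [SubstModel-class]; its \code{pi} is replaced by
#'   empirical frequencies unless \code{empiricalPi = FALSE}.
#' @param fitAlpha,fitKappa logical switches for the free parameters.
#' @param rounds alternation rounds.
#' @return list with \code{model}, \code{tree}, \code{logLik}.
#' @export
fitSubstModel <- function(aln, tree, model, fitAlpha = TRUE,
                          fitKappa = (model@model == "F84"),
                          empiricalPi = TRUE, rounds = 2L, tol = 1e-4) {
  if (empiricalPi) model@pi <- empiricalBaseFreqs(aln)
  if (fitAlpha && is.infinite(model@alpha)) {
    model@alpha <- 0.5
    model@nCategories <- 4L
  }
  for (r in seq_len(rounds)) {
    tree <- optimizeBranchLengths(aln, tree, models = model, tol = tol)
    if (fitAlpha) {
      opt <- optimize(function(a) {
        m2 <- model; m2@alpha <- a
        totalLogLik(aln, tree, m2)
      }, c(0.02, 50), maximum = TRUE, tol = 1e-3)
      model@alpha <- opt$maximum
    }
    if (fitKappa && model@model == "F84") {
      opt <- optimize(function(kp) {
        m2 <- model; m2@kappa <- kp
        totalLogLik(aln, tree, m2)
      }, c(0, 100), maximum = TRUE, tol = 1e-3)
      model@kappa <- opt$maximum
    }
  }
  tree <- optimizeBranchLengths(aln, tree, models = model, tol = tol)
  list(model = model, tree = tree, logLik = attr(tree, "logLik"))
}
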