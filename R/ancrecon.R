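# Mk1 (k-state, one-parameter) maximum-likelihood ancestral reconstruction
# of a discrete character, e.g. the four-state male sexual-parasitism
# coding: 0 = males never attach to females, 1 = attach temporarily,
# 2 = facultative parasites, 3 = obligate parasites.

#' Mk1 transition probability matrix
#'
#' Closed form for the k-state one-parameter model (k-state Jukes-Cantor):
#' \code{P_stay(t) = 1/k + (k-1)/k * exp(-k q t)} and
#' \code{P_change(t) = 1/k - 1/k * exp(-k q t)}.
#'
#' @param model an [MkModel-class].
#' @param t branch length, >= 0.
#' @return k x k row-stochastic matrix.
#' @examples
#' mkTransitionMatrix(mkModel(4, 0.25), 1)[1, 1]  # 0.25 + 0.75 * exp(-1)
#' @export
mkTransitionMatrix <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  k <- model@k
  e <- exp(-k * model@q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

# k x nTip tip partial matrix from a named state vector (0-based states;
# NA = missing -> all-ones).
.traitPartials <- function(trait, tipLabels, k) {
  part <- matrix(1, k, length(tipLabels))
  for (j in seq_along(tipLabels)) {
    s <- trait[[tipLabels[j]]]
    if (!is.null(s) && !is.na(s)) {
      if (s < 0 || s >= k) stop("state out of range for tip ", tipLabels[j])
      part[, j] <- 0
      part[s + 1L, j] <- 1
    }
  }
  part
}

# Downward (pruning) partials for every node; returns list(part, scaler)
# where part[[node]] is a k-vector and total lnL = log(sum(prior*part[root]))
# + sum(scalerLog).
.mkDownward <- function(tree, trait, model, scale = TRUE) {
  k <- model@k
  nTip <- ape::Ntip(tree)
  tree <- stats::reorder(tree, "postorder")
  tp <- .traitPartials(trait, tree$tip.label, k)
  part <- vector("list", nTip + tree$Nnode)
  for (j in seq_len(nTip)) part[[j]] <- tp[, j]
  scalerLog <- 0
  edge <- tree$edge
  i <- 1L; nE <- nrow(edge)
  Plist <- lapply(tree$edge.length, function(t) mkTransitionMatrix(model, t))
  while (i <= nE) {
    parent <- edge[i, 1]
    acc <- rep(1, k)
    while (i <= nE && edge[i, 1] == parent) {
      acc <- acc * as.numeric(Plist[[i]] %*% part[[edge[i, 2]]])
      i <- i + 1L
    }
    if (scale) {
      mx <- max(acc)
      if (mx > 0) { acc <- acc / mx; scalerLog <- scalerLog + log(mx) }
    }
    part[[parent]] <- acc
  }
  list(part = part, scalerLog = scalerLog, tree = tree, Plist = Plist)
}

#' Mk1 log-likelihood of a trait on a tree
#'
#' Pruning likelihood with a uniform 1/k root prior; missing tip states
#' integrate over all k states.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param trait named vector of 0-based states (NA = missing).
#' @param model an [MkModel-class].
#' @return total log-likelihood.
#' @export
mkLogLik <- function(tree, trait, model) {
  dw <- .mkDownward(tree, trait, model)
  root <- dw$tree$edge[nrow(dw$tree$edge), 1]
  log(mean(dw$part[[root]])) + dw$scalerLog
}

#' Fit the Mk1 rate by maximum likelihood
#'
#' 1-D bounded optimisation of the single Mk1 rate q on a fixed tree with
#' branch lengths (typically the molecular tree's substitution lengths).
#' If all observed states are identical the optimum is the q = 0 boundary
#' (no changes needed; lnL = log(1/k)) and the fit is flagged.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param trait named vector of 0-based states (NA = missing).
#' @param k number of states (default 4).
#' @param qMax upper bound of the search interval (default scales with the
#'   tree length so expected changes per branch stay finite).
#' @return list with \code{model} ([MkModel-class]), \code{logLik} and
#'   \code{boundary} flag.
#' @export
fitMk1 <- function(tree, trait, k = 4L, qMax = NULL) {
  obs <- trait[!is.na(trait)]
  if (is.null(qMax)) qMax <- 100 / mean(tree$edge.length)
  if (length(unique(obs)) < 2L) {
    model <- mkModel(k, 0)
    return(list(model = model, logLik = log(1 / k), boundary = TRUE))
  }
  f <- function(q) mkLogLik(tree, trait, mkModel(k, q))
  opt <- optimize(f, c(0, qMax), maximum = TRUE, tol = 1e-8)
  boundary <- opt$maximum < 1e-6 || opt$maximum > qMax * 0.999
  if (f(0) >= opt$objective) {
    return(list(model = mkModel(k, 0), logLik = f(0), boundary = TRUE))
  }
  list(model = mkModel(k, opt$maximum), logLik = opt$objective,
       boundary = boundary)
}

#' Marginal ancestral states under Mk1
#'
#' For every node, the normalised marginal likelihood of each state: the
#' joint likelihood of the tip data with that node's state fixed, computed
#' by combining downward (pruning) partials with the complementary
#' "outside" likelihoods in a single down-up pass, then normalising.  Tips
#' with observed states get unit vectors; nodes whose two best states are
#' within \code{equivocalMargin} are flagged equivocal.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param trait named vector of 0-based states (NA = missing).
#' @param model an [MkModel-class]; if missing, [fitMk1()] is run first.
#' @param equivocalMargin margin for the equivocal flag (default 0.05).
#' @return An [AncestralReconstruction-class]; \code{probs} rows follow ape
#'   node numbering (tips 1..n first, then internal nodes).
#' @export
marginalAncestralStates <- function(tree, trait, model = NULL,
                                    equivocalMargin = 0.05) {
  if (is.null(model)) {
    fit <- fitMk1(tree, trait, k = if (is.null(model)) 4L else model@k)
    model <- fit$model
  }
  k <- model@k
  # unscaled pass: keeps the exact identity
  # log(sum_s part_v(s) * outside_v(s)) = total lnL at every node v
  dw <- .mkDownward(tree, trait, model, scale = FALSE)
  po <- dw$tree
  edge <- po$edge
  nTip <- ape::Ntip(po)
  nTot <- nTip + po$Nnode
  root <- edge[nrow(edge), 1]
  prior <- rep(1 / k, k)
  # outside[v]: likelihood of all data NOT below v, as seen at v's states,
  # including the root prior.  Computed in preorder.
  outside <- vector("list", nTot)
  outside[[root]] <- prior
  childrenIdx <- split(seq_len(nrow(edge)), edge[, 1])
  for (i in rev(seq_len(nrow(edge)))) { # preorder over edges
    parent <- edge[i, 1]; child <- edge[i, 2]
    sibs <- setdiff(childrenIdx[[as.character(parent)]], i)
    acc <- outside[[parent]]
    for (j in sibs) acc <- acc * as.numeric(dw$Plist[[j]] %*% dw$part[[edge[j, 2]]])
    outside[[child]] <- as.numeric(crossprod(dw$Plist[[i]], acc))
  }
  # identity: for every node v, log(sum_s part_v(s) * outside_v(s)) +
  # scalerLog equals the total pruning log-likelihood
  probs <- matrix(NA_real_, nTot, k,
                  dimnames = list(NULL, paste0("state", 0:(k - 1))))
  for (v in seq_len(nTot)) {
    joint <- dw$part[[v]] * outside[[v]]
    probs[v, ] <- joint / sum(joint)
  }
  top2 <- t(apply(probs, 1, function(p) sort(p, decreasing = TRUE)[1:2]))
  equivocal <- (top2[, 1] - top2[, 2]) < equivocalMargin
  new("AncestralReconstruction", probs = probs, model = model,
      logLik = mkLogLik(tree, trait, model), equivocal = equivocal,
      boundary = model@q == 0)
}

#' Write a per-node ancestral-state probability table
#'
#' @param rec an [AncestralReconstruction-class].
#' @param tree the tree the reconstruction was computed on.
#' @param file output TSV path.
#' @return invisibly, \code{file}.
#' @export
writeAncestralTable <- function(rec, tree, file) {
  nTip <- ape::Ntip(tree)
  df <- data.frame(node = seq_len(nrow(rec@probs)),
                   label = c(tree$tip.label, rep("", tree$Nnode)),
                   rec@probs, equivocal = rec@equivocal)
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
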