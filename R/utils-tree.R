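# Tree helpers shared across modules.  Trees are ape "phylo" objects; an
# ultrametric tree with branch lengths in Myr doubles as a chronogram.

#' Node ages of a chronogram
#'
#' Ages (Myr before present) for every node of a rooted tree whose branch
#' lengths are durations; extant tips get age 0 (up to numerical tolerance).
#'
#' @param tree rooted \code{phylo} with branch lengths in Myr.
#' @return numeric vector of length \code{Ntip + Nnode}, indexed by ape node
#'   number.
#' @export
nodeAges <- function(tree) {
  if (!ape::is.rooted(tree)) stop("nodeAges() needs a rooted tree")
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

# parent lookup: parentOf[node] = parent node id, 0 for root
.parentOf <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# children lookup as a list indexed by node id
.childrenOf <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

.rootNode <- function(tree) ape::Ntip(tree) + 1L

# Phylogenetic diversity of a tip subset: sum of branch lengths of the
# induced subtree (root edges dropped by keep.tip's pruning).
.subtreePD <- function(tree, tips) {
  if (length(tips) < 2) return(0)
  sum(ape::keep.tip(tree, tips)$edge.length)
}

#' Round half-up at a fixed number of decimals
#'
#' The printed-table convention (base \code{round()} is half-to-even).
#'
#' @param x numeric vector.
#' @param d decimals.
#' @return rounded vector.
#' @export
roundHalfUp <- function(x, d = 0) floor(x * 10^d + 0.5 + 1e-12) / 10^d

# Moore-Penrose pseudo-inverse via SVD (used when a Hessian is singular).
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Project a symmetric matrix to the nearest positive semi-definite matrix by
# clamping negative eigenvalues.
.projectPSD <- function(A) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  A2 <- e$vectors %*% (lam * t(e$vectors))
  (A2 + t(A2)) / 2
}

# multiPhylo objects may compress tip labels into an attribute; extract
# elements through [[ so each phylo gets its labels back.
.asPhyloList <- function(x) {
  if (inherits(x, "phylo")) return(list(x))
  lapply(seq_along(x), function(i) x[[i]])
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
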