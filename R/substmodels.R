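# Rate-matrix machinery for the reversible nucleotide models.  States are
# ordered A, C, G, T throughout; Q is normalised to one expected substitution
# per site per unit branch length.

#' Discrete gamma rate categories
#'
#' Category rates for the standard equal-probability discretisation of a
#' Gamma(shape = alpha, mean = 1) distribution, each category represented by
#' its conditional mean.
#'
#' @param alpha gamma shape parameter (\code{Inf} returns a single unit rate).
#' @param k number of categories.
#' @return numeric vector of k rates with mean 1.
#' @export
discreteGammaRates <- function(alpha, k = 4L) {
  if (k == 1L || is.infinite(alpha)) return(1)
  bounds <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, pgamma(bounds, shape = alpha + 1, rate = alpha), 1)
  k * diff(p)
}

# Instantaneous rate matrix, normalised to unit mean rate.
.rateMatrix <- function(model) {
  pi <- model@pi
  if (model@model == "GTR") {
    S <- matrix(0, 4, 4)
    S[lower.tri(S)] <- model@exch[c(1, 2, 3, 4, 5, 6)]
    # order AC, AG, AT, CG, CT, GT fills (2,1),(3,1),(4,1),(3,2),(4,2),(4,3)
    S <- S + t(S)
  } else { # F84: transversions 1, transitions 1 + kappa / (frequency class)
    piR <- pi[1] + pi[3]
    piY <- pi[2] + pi[4]
    S <- matrix(1, 4, 4)
    S[1, 3] <- S[3, 1] <- 1 + model@kappa / piR  # A <-> G
    S[2, 4] <- S[4, 2] <- 1 + model@kappa / piY  # C <-> T
  }
  Q <- S * rep(pi, each = 4)   # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigendecomposition of the reversible Q via symmetrisation; returns an
# object from which P(t) = U1 %*% (exp(lambda t) * U2) is cheap.
.eigenQ <- function(model) {
  Q <- .rateMatrix(model)
  d <- sqrt(model@pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U1 = diag(1 / d) %*% e$vectors, U2 = t(e$vectors) %*% diag(d),
       lambda = e$values, Q = Q)
}

.probMatrix <- function(eig, t) {
  P <- eig$U1 %*% (exp(eig$lambda * t) * eig$U2)
  P[P < 0] <- 0
  P
}

# IUPAC nucleotide -> conditional likelihood vector over (A, C, G, T).
.NUC_CODES <- local({
  codes <- list(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), "-" = c(1, 1, 1, 1), "?" = c(1, 1, 1, 1))
  codes
})

# 4 x S conditional likelihood matrix for one taxon's site characters.
.tipPartials <- function(chars) {
  chars <- toupper(chars)
  unknown <- !(chars %in% names(.NUC_CODES))
  if (any(unknown))
    stop("unknown sequence symbol(s): ", paste(unique(chars[unknown]), collapse = " "))
  vapply(chars, function(s) .NUC_CODES[[s]], numeric(4))
}

#' Empirical base frequencies of an alignment
#'
#' Counts unambiguous A/C/G/T symbols (optionally within a subset of sites)
#' and returns their proportions; used to initialise \code{pi}.
#'
#' @param aln a [PartitionedAlignment-class].
#' @param sites optional site index subset.
#' @return numeric vector of 4 frequencies (A, C, G, T).
#' @export
empiricalBaseFreqs <- function(aln, sites = seq_len(nSites(aln))) {
  m <- toupper(alnMatrix(aln)[, sites, drop = FALSE])
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(m == b), numeric(1))
  if (sum(counts) == 0) return(rep(0.25, 4))
  unname(counts / sum(counts))
}
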