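# Topology testing from per-site log-likelihoods: RELL bootstrap
# proportions and the approximately unbiased (AU) test via the multiscale
# bootstrap (signed distance d and curvature c fitted across resample
# scales, p = 1 - Phi(d - c)).

# Seed policy shared by rellBootstrap and auTest so that the scale-1 column
# of an AU run is reproducible by a direct RELL call.
.rellSeed <- function(seed, scale) as.integer(seed) + as.integer(round(scale * 1000))

#' RELL bootstrap of per-site log-likelihoods
#'
#' Each replicate resamples \code{round(scale * m)} sites with replacement
#' (as a multinomial weight vector), sums the weighted per-site
#' log-likelihoods per tree and credits the best tree.  Replicates in which
#' k trees tie for the maximum credit 1/k to each, so counts always sum to
#' the number of replicates.
#'
#' @param table a [SiteLogLikTable-class].
#' @param replicates number of bootstrap replicates.
#' @param scale resample-size multiplier (1 = ordinary bootstrap).
#' @param seed integer seed (combined with \code{scale} via an internal
#'   policy so multiscale runs are reproducible per scale).
#' @return list with \code{counts} (per tree, summing to \code{replicates})
#'   and \code{bp} (bootstrap proportions).
#' @export
rellBootstrap <- function(table, replicates = 10000L, scale = 1, seed = 1L) {
  scores <- siteScores(table)
  if (nrow(scores) < 2L) stop("need at least two trees")
  m <- ncol(scores)
  if (m < 1L) stop("need at least one site")
  mm <- max(1L, as.integer(round(scale * m)))
  set.seed(.rellSeed(seed, scale))
  W <- rmultinom(replicates, mm, rep(1 / m, m)) # m x R
  tot <- scores %*% W                           # trees x R
  mx <- tot[1, ]
  for (i in seq_len(nrow(tot))[-1]) mx <- pmax(mx, tot[i, ])
  wins <- sweep(tot, 2, mx - 1e-10, ">=") + 0
  credit <- sweep(wins, 2, colSums(wins), "/")
  counts <- rowSums(credit)
  list(counts = setNames(counts, rownames(scores)),
       bp = setNames(counts / replicates, rownames(scores)))
}

#' Approximately unbiased (AU) topology test
#'
#' Runs the RELL bootstrap at several resample scales r, fits the
#' probit-transformed bootstrap proportions of each tree by weighted least
#' squares to \code{qnorm(1 - bp(r)) = d*sqrt(r) + c/sqrt(r)} (signed
#' distance d, curvature c) and reports \code{p_au = 1 - Phi(d - c)}.  The
#' WLS weights are the delta-method variances of the probit transform,
#' \code{B * phi(z)^2 / (bp (1 - bp))}.  Scales at which a tree's bp is
#' exactly 0 or 1 carry no curvature information and are dropped; a tree
#' with fewer than two informative scales gets a degenerate-fit flag and a
#' p-value clamped to 0 or 1.
#'
#' @param table a [SiteLogLikTable-class].
#' @param scales resample-scale multipliers (default the ten CONSEL scales
#'   0.5 ... 1.4).
#' @param replicates bootstrap replicates per scale.
#' @param seed integer seed.
#' @return data.frame with one row per tree: \code{tree, diff_lnL, bp}
#'   (at scale 1 if present, else nearest scale), \code{d, c, p_au,
#'   degenerate}.
#' @export
auTest <- function(table, scales = seq(0.5, 1.4, by = 0.1),
                   replicates = 10000L, seed = 1L) {
  scores <- siteScores(table)
  nT <- nrow(scores)
  bpMat <- vapply(scales, function(s)
    rellBootstrap(table, replicates, scale = s, seed = seed)$bp, numeric(nT))
  bpMat <- matrix(bpMat, nrow = nT,
                  dimnames = list(rownames(scores), paste0("r", scales)))
  refScale <- which.min(abs(scales - 1))
  tot <- rowSums(scores)
  out <- data.frame(tree = rownames(scores), diff_lnL = max(tot) - tot,
                    bp = bpMat[, refScale], d = NA_real_, c = NA_real_,
                    p_au = NA_real_, degenerate = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nT)) {
    bp <- bpMat[i, ]
    use <- bp > 0 & bp < 1
    if (sum(use) < 2L) {
      out$degenerate[i] <- TRUE
      out$p_au[i] <- if (mean(bp) > 0.5) 1 else 0
      next
    }
    z <- qnorm(1 - bp[use])
    w <- replicates * dnorm(z)^2 / (bp[use] * (1 - bp[use]))
    X <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
    XtW <- t(X * w)
    coef <- solve(XtW %*% X, XtW %*% z)
    out$d[i] <- coef[1]
    out$c[i] <- coef[2]
    out$p_au[i] <- 1 - pnorm(coef[1] - coef[2])
  }
  out
}

#' Ranked hypothesis comparison table
#'
#' Formats AU-test results for a set of constrained/unconstrained candidate
#' topologies as the usual ranked table: log-likelihood deficit against the
#' best tree, AU p-value, and a rejection flag at the chosen level.
#'
#' @param table a [SiteLogLikTable-class] whose rows are the hypotheses.
#' @param labels optional hypothesis labels (default the table rownames).
#' @param alpha rejection level (default 0.05).
#' @param ... passed to [auTest()].
#' @return data.frame sorted by \code{diff_lnL}: \code{hypothesis, diff_lnL,
#'   bp, p_au, rejected}.
#' @export
topologyReport <- function(table, labels = NULL, alpha = 0.05, ...) {
  res <- auTest(table, ...)
  if (!is.null(labels)) res$tree <- labels
  out <- data.frame(hypothesis = res$tree, diff_lnL = res$diff_lnL,
                    bp = res$bp, p_au = res$p_au,
                    rejected = res$p_au < alpha, stringsAsFactors = FALSE)
  out[order(out$diff_lnL), , drop = FALSE]
}

# Exhaustive RELL expectation for tiny site counts: enumerate all
# multinomial resamples of m sites and accumulate each tree's win
# probability (fractional ties).  Oracle-grade; cost is choose(m+m-1, m).
.rellExact <- function(table, scale = 1) {
  scores <- siteScores(table)
  m <- ncol(scores)
  mm <- max(1L, as.integer(round(scale * m)))
  counts <- .compositions(mm, m)
  probs <- apply(counts, 1, function(k)
    exp(lgamma(mm + 1) - sum(lgamma(k + 1)) - mm * log(m)))
  bp <- numeric(nrow(scores))
  for (i in seq_len(nrow(counts))) {
    tot <- scores %*% counts[i, ]
    win <- tot >= max(tot) - 1e-10
    bp[win] <- bp[win] + probs[i] / sum(win)
  }
  setNames(bp, rownames(scores))
}

# All compositions of n into k non-negative parts (rows).
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    sub <- .compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}
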