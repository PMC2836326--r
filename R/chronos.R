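# Bayesian relaxed-clock divergence dating in the two-step multidivtime
# style: per-partition branch lengths and their covariance are estimated
# first (see estimateBranchCovariance), then an MCMC samples node ages and
# autocorrelated log-normal rates, with the multivariate-normal density of
# the estimated branch lengths around their expected values (duration times
# mean endpoint rate) standing in for the full sequence likelihood.

#' Priors for the dating MCMC
#'
#' Accepts the conventional multidivtime parameterisation, where time is
#' counted in units of \code{timeUnit} Myr (100 by default, so
#' \code{rttm = 4.2} means 420 Myr), and converts everything to Myr-based
#' units used internally: ages in Myr, rates in substitutions/site/Myr, and
#' the Brownian variance of the log rate per Myr.
#'
#' @param rttm,rttmsd prior mean and sd of the root age (in \code{timeUnit}
#'   Myr).
#' @param rtrate,rtratesd prior mean and sd of the root-node rate
#'   (substitutions/site per \code{timeUnit} Myr); may be NULL to be derived
#'   later via [deriveRootRatePrior()].
#' @param brownmean,brownsd prior mean and sd of the Brownian variance
#'   parameter nu (per \code{timeUnit} Myr).
#' @param timeUnit Myr per time unit (default 100).
#' @return list of priors in Myr units: \code{rttm, rttmsd, rtrate,
#'   rtratesd, brownmean, brownsd}.
#' @examples
#' chronosPriors(rttm = 4.2, rttmsd = 4.2, rtrate = 0.074, rtratesd = 0.074)
#' @export
chronosPriors <- function(rttm = 4.2, rttmsd = 4.2, rtrate = NULL,
                          rtratesd = NULL, brownmean = 0.5, brownsd = 0.5,
                          timeUnit = 100) {
  stopifnot(rttm > 0, rttmsd > 0, brownmean > 0, brownsd > 0)
  list(rttm = rttm * timeUnit, rttmsd = rttmsd * timeUnit,
       rtrate = if (!is.null(rtrate)) rtrate / timeUnit,
       rtratesd = if (!is.null(rtratesd)) rtratesd / timeUnit,
       brownmean = brownmean / timeUnit, brownsd = brownsd / timeUnit)
}

#' Chain settings for the dating MCMC
#'
#' Defaults follow the conventional multidivtime schedule: a burn-in of
#' 100,000 cycles, then 10,000 retained samples taken every 100 cycles.
#' Desk-scale analyses (tests, vignette) pass much shorter chains.
#'
#' @param burnin burn-in cycles (one cycle = one full proposal sweep).
#' @param samples number of retained samples.
#' @param thin cycles between retained samples.
#' @param priorOnly if TRUE the branch-length likelihood is switched off
#'   (prior-predictive run).
#' @param meanCorrection subtract nu*dt/2 from the child log-rate mean (the
#'   stationary-mean-rate convention); default FALSE.
#' @param rateSd,nuSd random-walk sd for node log-rates and log-nu.
#' @param scaleDelta half-width of the whole-tree log-scale move.
#' @param rootSlideFrac root-age slide half-width as a fraction of the prior
#'   mean root age.
#' @param negativeLengths how to treat negative estimated branch lengths:
#'   \code{"clamp"} to zero (default, the common multidivtime practice),
#'   \code{"keep"} them as-is (consistent with the MVN approximation), or
#'   \code{"error"} to reject the input.
#' @return list of settings.
#' @export
chronosSettings <- function(burnin = 100000L, samples = 10000L, thin = 100L,
                            priorOnly = FALSE, meanCorrection = FALSE,
                            rateSd = 0.3, nuSd = 0.5, scaleDelta = 0.1,
                            rootSlideFrac = 0.05,
                            negativeLengths = c("clamp", "keep", "error")) {
  list(burnin = as.integer(burnin), samples = as.integer(samples),
       thin = as.integer(thin), priorOnly = priorOnly,
       meanCorrection = meanCorrection, rateSd = rateSd, nuSd = nuSd,
       scaleDelta = scaleDelta, rootSlideFrac = rootSlideFrac,
       negativeLengths = match.arg(negativeLengths))
}

#' Derive the root-rate prior from tip-to-root path lengths
#'
#' The mean over tips of the tip-to-root path length (expected
#' substitutions/site) divided by the prior mean root age gives the prior
#' mean of the root-node rate; the prior sd is set equal to the mean.
#'
#' @param tree rooted \code{phylo} with branch lengths in subst/site.
#' @param rttm prior mean root age (any time unit; the returned rate is per
#'   that unit).
#' @return list with \code{rtrate} and \code{rtratesd}.
#' @export
deriveRootRatePrior <- function(tree, rttm) {
  if (!ape::is.rooted(tree)) stop("deriveRootRatePrior() needs a rooted tree")
  depth <- ape::node.depth.edgelength(tree)
  rt <- mean(depth[seq_len(ape::Ntip(tree))]) / rttm
  list(rtrate = rt, rtratesd = rt)
}

#' Resolve calibration constraints to ape node numbers
#'
#' Each constraint identifies a node as the most recent common ancestor of a
#' named taxon set.  A set of more than two taxa must be monophyletic in the
#' topology, otherwise the constraint is rejected.
#'
#' @param tree rooted \code{phylo}.
#' @param constraints data.frame with columns \code{taxa}
#'   (semicolon-separated tip labels), \code{lower}, \code{upper} (Myr; NA =
#'   unbounded).
#' @return data.frame with columns \code{node, lower, upper}.
#' @export
resolveConstraints <- function(tree, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0)
    return(data.frame(node = integer(0), lower = numeric(0), upper = numeric(0)))
  node <- integer(nrow(constraints))
  for (i in seq_len(nrow(constraints))) {
    taxa <- strsplit(constraints$taxa[i], ";")[[1]]
    taxa <- trimws(taxa[nzchar(trimws(taxa))])
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
      stop("constraint taxa not in tree: ", paste(missing, collapse = ", "))
    if (length(taxa) > 2 && !ape::is.monophyletic(tree, taxa))
      stop("constraint on a non-monophyletic taxon set: ",
           constraints$taxa[i])
    node[i] <- if (length(taxa) == 1) match(taxa, tree$tip.label)
               else ape::getMRCA(tree, taxa)
  }
  data.frame(node = node, lower = constraints$lower, upper = constraints$upper)
}

# Propagate bounds over the tree; errors on an infeasible set.
.effectiveBounds <- function(tree, constraints) {
  nTip <- ape::Ntip(tree)
  nTot <- nTip + tree$Nnode
  lb <- rep(0, nTot)
  ub <- rep(Inf, nTot)
  if (nrow(constraints)) {
    for (i in seq_len(nrow(constraints))) {
      v <- constraints$node[i]
      if (!is.na(constraints$lower[i])) lb[v] <- max(lb[v], constraints$lower[i])
      if (!is.na(constraints$upper[i])) ub[v] <- min(ub[v], constraints$upper[i])
    }
  }
  po <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) lb[po[i, 1]] <- max(lb[po[i, 1]], lb[po[i, 2]])
  for (i in rev(seq_len(nrow(po)))) ub[po[i, 2]] <- min(ub[po[i, 2]], ub[po[i, 1]])
  bad <- which(lb > ub + 1e-9)
  if (length(bad))
    stop("infeasible calibration constraints at node(s) ",
         paste(bad, collapse = ", "),
         ": propagated lower bound exceeds upper bound")
  list(lb = lb, ub = ub)
}

# Feasible initial ages (postorder fill between effective bounds).
.initAges <- function(tree, bounds, rttm) {
  nTip <- ape::Ntip(tree)
  nTot <- nTip + tree$Nnode
  ages <- numeric(nTot)
  po <- stats::reorder(tree, "postorder")$edge
  inc <- rttm / (2 * tree$Nnode)
  parents <- unique(po[, 1])
  childrenOf <- split(po[, 2], po[, 1])
  for (v in parents) { # postorder guarantees children first
    lo <- max(c(ages[childrenOf[[as.character(v)]]], bounds$lb[v]))
    hi <- bounds$ub[v]
    ages[v] <- if (is.finite(hi)) lo + 0.5 * (hi - lo) else lo + inc
  }
  ages
}

#' Run the relaxed-clock dating MCMC
#'
#' Metropolis-Hastings sampling of internal-node ages, per-partition node
#' log-rates and per-partition Brownian variances nu.  The likelihood of a
#' state is the multivariate-normal density of each partition's estimated
#' branch lengths around their expected values (branch duration times the
#' arithmetic mean of the endpoint node rates), using the estimated
#' branch-length covariance; partitions are unlinked.  Priors: gamma on the
#' root age (mean \code{rttm}, sd \code{rttmsd}) truncated by the
#' calibration bounds, gamma on each partition's root-node rate, gamma on
#' each nu, Brownian-motion transition densities on the log rates, and a
#' flat prior on the ordered internal ages given the root.  Proposals:
#' per-node age draws uniform in the locally feasible interval, random-walk
#' log-rates, random-walk log-nu, and a whole-tree age scaling.  Every
#' retained sample satisfies every calibration bound by construction.
#'
#' @param estimates one partition's \code{list(lengths, vcov)} (edge order
#'   of \code{tree}), or a list of such lists for several partitions.
#' @param tree rooted topology (\code{phylo}); its branch lengths are
#'   ignored, only edge order matters.
#' @param constraints data.frame(node, lower, upper) from
#'   [resolveConstraints()], or NULL.
#' @param priors Myr-unit prior list from [chronosPriors()] (with
#'   \code{rtrate}/\code{rtratesd} set).
#' @param settings from [chronosSettings()].
#' @param seed integer seed; the chain is a deterministic function of it.
#' @return A [ChronosPosterior-class].
#' @export
runDatingMCMC <- function(estimates, tree, constraints = NULL,
                          priors = chronosPriors(), settings = chronosSettings(),
                          seed = 1L) {
  if (!ape::is.rooted(tree)) stop("dating needs a rooted topology")
  if (!is.null(estimates$lengths)) estimates <- list(estimates)
  nPart <- length(estimates)
  if (is.null(priors$rtrate) || is.null(priors$rtratesd))
    stop("priors$rtrate/rtratesd missing; derive them with deriveRootRatePrior()")
  nTip <- ape::Ntip(tree)
  nTot <- nTip + tree$Nnode
  root <- .rootNode(tree)
  internal <- (nTip + 1L):nTot
  edge <- tree$edge
  if (is.null(constraints))
    constraints <- data.frame(node = integer(0), lower = numeric(0),
                              upper = numeric(0))
  bounds <- .effectiveBounds(tree, constraints)
  parentOf <- .parentOf(tree)
  childrenOf <- .childrenOf(tree)

  Sinv <- vector("list", nPart)
  bhat <- vector("list", nPart)
  for (p in seq_len(nPart)) {
    b <- estimates[[p]]$lengths
    if (length(b) != nrow(edge)) stop("branch estimates do not match the tree edges")
    if (any(b < 0)) {
      b <- switch(settings$negativeLengths,
        clamp = pmax(b, 0),
        keep = b,
        error = stop("negative estimated branch lengths"))
    }
    bhat[[p]] <- b
    V <- .projectPSD(estimates[[p]]$vcov)
    Sinv[[p]] <- tryCatch(solve(V), error = function(e) .pinv(V))
  }

  gshape <- function(m, s) (m / s)^2
  grate <- function(m, s) m / s^2
  ageShape <- gshape(priors$rttm, priors$rttmsd)
  ageRate <- grate(priors$rttm, priors$rttmsd)
  rShape <- gshape(priors$rtrate, priors$rtratesd)
  rRate <- grate(priors$rtrate, priors$rtratesd)
  nuShape <- gshape(priors$brownmean, priors$brownsd)
  nuRate <- grate(priors$brownmean, priors$brownsd)

  pa <- edge[, 1]; ch <- edge[, 2]
  intNonRoot <- setdiff(internal, root)
  # nodes pinned by a degenerate L = U constraint carry a point mass, not a
  # uniform density
  intNonRoot <- intNonRoot[bounds$ub[intNonRoot] - bounds$lb[intNonRoot] > 1e-9]
  paInt <- parentOf[intNonRoot]
  logPost <- function(ages, logr, lognu) {
    dur <- ages[pa] - ages[ch]
    if (any(dur < -1e-12)) return(-Inf)
    dur <- pmax(dur, 0)
    lp <- stats::dgamma(ages[root], ageShape, ageRate, log = TRUE)
    # proper preorder-uniform prior on the other internal ages: each node
    # uniform between its effective bounds below its parent, so the root
    # marginal stays exactly the (truncated) gamma
    if (length(intNonRoot)) {
      width <- pmin(ages[paInt], bounds$ub[intNonRoot]) - bounds$lb[intNonRoot]
      if (any(width <= 0)) return(-Inf)
      lp <- lp - sum(log(width))
    }
    durSafe <- pmax(dur, 1e-8)
    for (p in seq_len(nPart)) {
      rates <- exp(logr[, p])
      if (!settings$priorOnly) {
        mu <- (rates[pa] + rates[ch]) / 2 * dur
        resid <- bhat[[p]] - mu
        lp <- lp - 0.5 * sum(resid * (Sinv[[p]] %*% resid))
      }
      nu <- exp(lognu[p])
      mc <- if (settings$meanCorrection) nu * durSafe / 2 else 0
      lp <- lp + sum(dnorm(logr[ch, p], logr[pa, p] - mc,
                           sqrt(nu * durSafe), log = TRUE))
      lp <- lp + stats::dgamma(rates[root], rShape, rRate, log = TRUE) +
        logr[root, p]
      lp <- lp + stats::dgamma(nu, nuShape, nuRate, log = TRUE) + lognu[p]
    }
    lp
  }

  set.seed(as.integer(seed))
  ages <- .initAges(tree, bounds, priors$rttm)
  logr <- matrix(log(priors$rtrate), nTot, nPart)
  lognu <- rep(log(priors$brownmean), nPart)
  cur <- logPost(ages, logr, lognu)
  if (!is.finite(cur)) stop("could not initialise a finite posterior state")

  # --- cached quantities for incremental (delta) posterior updates -------
  nE <- nrow(edge)
  adjEdges <- lapply(seq_len(nTot), function(v) which(pa == v | ch == v))
  widthIdxByNode <- lapply(seq_len(nTot), function(v) which(paInt == v))
  ubInt <- bounds$ub[intNonRoot]; lbInt <- bounds$lb[intNonRoot]
  priorOnly <- settings$priorOnly
  meanCorr <- settings$meanCorrection
  lbI <- bounds$lb[internal]; ubI <- bounds$ub[internal]

  dur <- durSafe <- NULL; rates <- NULL
  mu <- r <- Sr <- vector("list", nPart); quad <- numeric(nPart)
  bm <- vector("list", nPart)
  widthLog <- NULL; rootAgeLog <- NULL
  rootRateLog <- nuLog <- numeric(nPart)

  bmVec <- function(p, eIdx, durS) {
    nu <- exp(lognu[p])
    mc <- if (meanCorr) nu * durS / 2 else 0
    dnorm(logr[ch[eIdx], p], logr[pa[eIdx], p] - mc, sqrt(nu * durS),
          log = TRUE)
  }
  rebuild <- function(check = FALSE) {
    old <- cur
    dur <<- pmax(ages[pa] - ages[ch], 0)
    durSafe <<- pmax(dur, 1e-8)
    rates <<- exp(logr)
    rootAgeLog <<- stats::dgamma(ages[root], ageShape, ageRate, log = TRUE)
    widthLog <<- if (length(intNonRoot))
      log(pmin(ages[paInt], ubInt) - lbInt) else numeric(0)
    for (p in seq_len(nPart)) {
      if (!priorOnly) {
        mu[[p]] <<- (rates[pa, p] + rates[ch, p]) / 2 * dur
        r[[p]] <<- bhat[[p]] - mu[[p]]
        Sr[[p]] <<- as.numeric(Sinv[[p]] %*% r[[p]])
        quad[p] <<- sum(r[[p]] * Sr[[p]])
      } else quad[p] <<- 0
      bm[[p]] <<- bmVec(p, seq_len(nE), durSafe)
      rootRateLog[p] <<- stats::dgamma(rates[root, p], rShape, rRate,
                                       log = TRUE) + logr[root, p]
      nuLog[p] <<- stats::dgamma(exp(lognu[p]), nuShape, nuRate, log = TRUE) +
        lognu[p]
    }
    cur <<- rootAgeLog - sum(widthLog) +
      sum(-0.5 * quad + vapply(bm, sum, numeric(1)) + rootRateLog + nuLog)
    if (check && is.finite(old) && abs(old - cur) > 1e-4)
      stop("internal error: incremental posterior drifted by ", old - cur)
  }
  rebuild()

  nKeep <- settings$samples
  keepAges <- matrix(NA_real_, nKeep, length(internal),
                     dimnames = list(NULL, internal))
  keepRates <- matrix(NA_real_, nKeep, nTot)
  keepNu <- matrix(NA_real_, nKeep, nPart)
  kept <- 0L
  totalCycles <- settings$burnin + nKeep * settings$thin
  rootW <- priors$rttm * settings$rootSlideFrac

  for (cycle in seq_len(totalCycles)) {
    # node-age moves: a global draw over the feasible interval plus a local
    # slide (the draw crosses modes, the slide resolves sharp posteriors)
    for (v in internal) {
      lo <- max(c(ages[childrenOf[[v]]], bounds$lb[v]))
      hi <- if (v == root) bounds$ub[v] else min(ages[parentOf[v]], bounds$ub[v])
      if (hi - lo < 1e-12) next
      E <- adjEdges[[v]]
      wIdx <- widthIdxByNode[[v]]
      for (move in 1:2) {
        newAge <- if (move == 1L) {
          if (is.finite(hi)) runif(1, lo, hi)
          else ages[v] + runif(1, -rootW, rootW)
        } else {
          # multi-scale local slide: width spans two decades so both sharp
          # and diffuse conditionals get acceptable proposals
          w <- (if (is.finite(hi)) hi - lo else rootW) * 10^runif(1, -2, -0.5)
          ages[v] + runif(1, -w, w)
        }
        if (newAge < lo || newAge > hi) next
        newDur <- ifelse(pa[E] == v, newAge - ages[ch[E]],
                         ages[pa[E]] - newAge)
        newDur <- pmax(newDur, 0)
        newDurS <- pmax(newDur, 1e-8)
        dlp <- 0
        if (v == root) {
          newRootAgeLog <- stats::dgamma(newAge, ageShape, ageRate, log = TRUE)
          dlp <- dlp + newRootAgeLog - rootAgeLog
        }
        newWidth <- NULL
        if (length(wIdx)) {
          newWidth <- log(pmin(newAge, ubInt[wIdx]) - lbInt[wIdx])
          dlp <- dlp - sum(newWidth) + sum(widthLog[wIdx])
        }
        newMuE <- newBmE <- vector("list", nPart)
        dQuad <- numeric(nPart)
        for (p in seq_len(nPart)) {
          if (!priorOnly) {
            newMuE[[p]] <- (rates[pa[E], p] + rates[ch[E], p]) / 2 * newDur
            del <- mu[[p]][E] - newMuE[[p]]
            dQuad[p] <- 2 * sum(del * Sr[[p]][E]) +
              sum(del * (Sinv[[p]][E, E, drop = FALSE] %*% del))
            dlp <- dlp - 0.5 * dQuad[p]
          }
          newBmE[[p]] <- bmVec(p, E, newDurS)
          dlp <- dlp + sum(newBmE[[p]]) - sum(bm[[p]][E])
        }
        if (is.finite(dlp) && log(runif(1)) < dlp) {
          ages[v] <- newAge
          dur[E] <- newDur; durSafe[E] <- newDurS
          if (v == root) rootAgeLog <- newRootAgeLog
          if (length(wIdx)) widthLog[wIdx] <- newWidth
          for (p in seq_len(nPart)) {
            if (!priorOnly) {
              del <- mu[[p]][E] - newMuE[[p]]
              mu[[p]][E] <- newMuE[[p]]
              r[[p]][E] <- bhat[[p]][E] - newMuE[[p]]
              Sr[[p]] <- Sr[[p]] + as.numeric(Sinv[[p]][, E, drop = FALSE] %*% del)
              quad[p] <- quad[p] + dQuad[p]
            }
            bm[[p]][E] <- newBmE[[p]]
          }
          cur <- cur + dlp
        }
      }
    }
    # log-rate moves
    for (p in seq_len(nPart)) {
      for (v in seq_len(nTot)) {
        newLogr <- logr[v, p] + rnorm(1, 0, settings$rateSd)
        E <- adjEdges[[v]]
        oldLogr <- logr[v, p]; oldRate <- rates[v, p]
        logr[v, p] <- newLogr; rates[v, p] <- exp(newLogr)
        dlp <- 0
        newMuE <- NULL; dQuad <- 0
        if (!priorOnly) {
          newMuE <- (rates[pa[E], p] + rates[ch[E], p]) / 2 * dur[E]
          del <- mu[[p]][E] - newMuE
          dQuad <- 2 * sum(del * Sr[[p]][E]) +
            sum(del * (Sinv[[p]][E, E, drop = FALSE] %*% del))
          dlp <- dlp - 0.5 * dQuad
        }
        newBmE <- bmVec(p, E, durSafe[E])
        dlp <- dlp + sum(newBmE) - sum(bm[[p]][E])
        newRootRateLog <- NULL
        if (v == root) {
          newRootRateLog <- stats::dgamma(rates[root, p], rShape, rRate,
                                          log = TRUE) + newLogr
          dlp <- dlp + newRootRateLog - rootRateLog[p]
        }
        if (is.finite(dlp) && log(runif(1)) < dlp) {
          if (!priorOnly) {
            del <- mu[[p]][E] - newMuE
            mu[[p]][E] <- newMuE
            r[[p]][E] <- bhat[[p]][E] - newMuE
            Sr[[p]] <- Sr[[p]] + as.numeric(Sinv[[p]][, E, drop = FALSE] %*% del)
            quad[p] <- quad[p] + dQuad
          }
          bm[[p]][E] <- newBmE
          if (v == root) rootRateLog[p] <- newRootRateLog
          cur <- cur + dlp
        } else {
          logr[v, p] <- oldLogr; rates[v, p] <- oldRate
        }
      }
      # nu move: the Brownian densities of this partition change wholesale
      oldLognu <- lognu[p]
      lognu[p] <- lognu[p] + rnorm(1, 0, settings$nuSd)
      newBmAll <- bmVec(p, seq_len(nE), durSafe)
      newNuLog <- stats::dgamma(exp(lognu[p]), nuShape, nuRate, log = TRUE) +
        lognu[p]
      dlp <- sum(newBmAll) - sum(bm[[p]]) + newNuLog - nuLog[p]
      if (is.finite(dlp) && log(runif(1)) < dlp) {
        bm[[p]] <- newBmAll
        nuLog[p] <- newNuLog
        cur <- cur + dlp
      } else lognu[p] <- oldLognu
    }
    # whole-tree scaling: ages alone, then ages with rates counter-scaled
    # (the second travels along the age x rate likelihood ridge)
    for (joint in c(FALSE, TRUE)) {
      u <- runif(1, -settings$scaleDelta, settings$scaleDelta)
      sc <- exp(u)
      agesI2 <- ages[internal] * sc
      ok <- all(agesI2 >= lbI - 1e-12) && all(agesI2 <= ubI + 1e-12)
      if (!ok) next
      ages2 <- ages; ages2[internal] <- agesI2
      logr2 <- if (joint) logr - u else logr
      new <- logPost(ages2, logr2, lognu)
      if (log(runif(1)) < new - cur + length(internal) * u) {
        ages <- ages2; logr <- logr2
        rebuild()  # refresh every cache (also resets accumulated drift)
      }
    }
    if (cycle %% 1000L == 0L) rebuild(check = TRUE)
    if (cycle > settings$burnin &&
        (cycle - settings$burnin) %% settings$thin == 0L) {
      kept <- kept + 1L
      keepAges[kept, ] <- ages[internal]
      keepRates[kept, ] <- rates[, 1]
      keepNu[kept, ] <- exp(lognu)
    }
  }

  qs <- apply(keepAges, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  summ <- data.frame(node = internal, mean = colMeans(keepAges),
                     lower = qs[1, ], upper = qs[2, ])
  new("ChronosPosterior", ages = keepAges, rates = keepRates,
      nu = keepNu, summary = summ, settings = settings,
      priors = priors, constraints = constraints, seed = as.integer(seed),
      rhat = NA_real_, converged = NA)
}

#' Split-Rhat over replicate chains
#'
#' Gelman-Rubin potential scale reduction computed after splitting each
#' chain in half (so a single drifting chain is also detected).
#'
#' @param ... numeric vectors, one retained-sample trace per chain.
#' @return the split-Rhat statistic.
#' @export
splitRhat <- function(...) {
  chains <- list(...)
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}

#' Two-step divergence dating from an alignment
#'
#' The full two-step workflow: per dating partition (first+second codon
#' positions merged, rRNA, tRNA; third codon positions are excluded
#' entirely), fit an F84+Gamma model and branch lengths on the fixed
#' topology, estimate the branch-length covariance, then run the dating
#' MCMC.  At least two replicate chains with distinct seeds are run and
#' convergence is diagnosed by the split-Rhat of the root age.
#'
#' @param aln a [PartitionedAlignment-class].
#' @param tree rooted topology (\code{phylo}).
#' @param constraints calibration data.frame (see [resolveConstraints()];
#'   may already be resolved to node numbers).
#' @param priors from [chronosPriors()]; if \code{rtrate} is NULL it is
#'   derived from the fitted branch lengths via [deriveRootRatePrior()].
#' @param settings from [chronosSettings()].
#' @param seed integer seed; chain i uses \code{seed + i - 1}.
#' @param nChains number of replicate chains (>= 2).
#' @return A [ChronosPosterior-class] with samples pooled across chains and
#'   the \code{rhat}/\code{converged} slots filled.
#' @export
twoStepDate <- function(aln, tree, constraints = NULL,
                        priors = chronosPriors(), settings = chronosSettings(),
                        seed = 1L, nChains = 2L) {
  part <- sitePartition(aln)
  keep <- part != "codon3"
  aln2 <- aln[, keep]
  part2 <- sitePartition(aln2)
  grouping <- ifelse(part2 %in% c("codon1", "codon2"), "codon12", part2)
  estimates <- list()
  rtrates <- numeric(0)
  for (g in unique(grouping)) {
    sub <- aln2[, grouping == g]
    fit <- fitSubstModel(sub, tree, substModel("F84", alpha = 0.5),
                         rounds = 1L, tol = 1e-3)
    est <- estimateBranchCovariance(sub, tree, fit$model, tol = 1e-4)
    estimates[[g]] <- list(lengths = est$lengths, vcov = est$vcov)
    rtrates <- c(rtrates, deriveRootRatePrior(est$tree, priors$rttm)$rtrate)
  }
  if (is.null(priors$rtrate)) {
    priors$rtrate <- mean(rtrates)
    priors$rtratesd <- mean(rtrates)
  }
  if (!is.null(constraints) && is.null(constraints$node))
    constraints <- resolveConstraints(tree, constraints)
  chains <- lapply(seq_len(nChains), function(i)
    runDatingMCMC(estimates, tree, constraints, priors, settings,
                  seed = as.integer(seed) + i - 1L))
  pooledAges <- do.call(rbind, lapply(chains, ageSamples))
  pooled <- chains[[1]]
  pooled@ages <- pooledAges
  pooled@rates <- do.call(rbind, lapply(chains, function(c) c@rates))
  pooled@nu <- do.call(rbind, lapply(chains, function(c) c@nu))
  qs <- apply(pooledAges, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  pooled@summary <- data.frame(node = as.integer(colnames(pooledAges)),
                               mean = colMeans(pooledAges),
                               lower = qs[1, ], upper = qs[2, ])
  rootCol <- 1L
  pooled@rhat <- do.call(splitRhat,
                         lapply(chains, function(c) ageSamples(c)[, rootCol]))
  pooled@converged <- is.finite(pooled@rhat) && pooled@rhat <= 1.1
  pooled
}

#' Chronogram from a posterior
#'
#' Sets the branch lengths of the topology to posterior-mean durations, so
#' the result is an ultrametric tree in Myr.
#'
#' @param posterior a [ChronosPosterior-class].
#' @param tree the rooted topology the MCMC was run on.
#' @return a \code{phylo} chronogram.
#' @export
posteriorChronogram <- function(posterior, tree) {
  ages <- numeric(ape::Ntip(tree) + tree$Nnode)
  ages[posterior@summary$node] <- posterior@summary$mean
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree
}
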