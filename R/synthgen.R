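# Synthetic-data generators: birth-death chronograms, geometric Brownian
# rate trajectories, partitioned sequence alignments and Mk traits.  Every
# generator is a pure function of its parameters and a seed, so downstream
# stages are testable without any external data.

#' Simulate a birth-death chronogram
#'
#' Gillespie simulation of a constant-rate birth-death process started from
#' two crown lineages, run until \code{tMax} Myr (or until \code{nTarget}
#' extant lineages exist), then pruned to the reconstructed tree of
#' survivors.  Tip ages are exactly 0 and node ages are in Myr.
#'
#' @param b speciation rate (events/lineage/Myr), > 0.
#' @param d extinction rate (events/lineage/Myr), 0 <= d <= b.
#' @param tMax simulation span in Myr.
#' @param nTarget optional: stop as soon as this many lineages are extant.
#' @param seed integer seed.
#' @return a rooted ultrametric \code{phylo}; \code{attr(,"stemAge")} holds
#'   the elapsed simulation time.
#' @section Errors: if the process dies out (fewer than two survivors) a
#'   condition of class \code{"lophiphy_extinct"} is signalled rather than an
#'   empty tree being returned.
#' @examples
#' tr <- simulateBDTree(b = 0.1, d = 0, tMax = 30, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulateBDTree <- function(b, d = 0, tMax, nTarget = NULL, seed) {
  stopifnot(b > 0, d >= 0, d <= b, tMax > 0)
  set.seed(as.integer(seed))
  maxL <- 64L
  parent <- integer(maxL); tBirth <- numeric(maxL); tEnd <- numeric(maxL)
  status <- integer(maxL) # 0 alive, 1 extinct, 2 split
  nL <- 2L
  parent[1:2] <- 0L; tBirth[1:2] <- 0; status[1:2] <- 0L
  alive <- integer(maxL)
  alive[1:2] <- c(1L, 2L)
  nAlive <- 2L
  t <- 0
  repeat {
    if (nAlive == 0L) break
    dt <- rexp(1, nAlive * (b + d))
    if (!is.null(nTarget) && nAlive >= nTarget) {
      # stop while nTarget lineages exist, at the would-be next event time,
      # so terminal branches keep positive length
      tMax <- min(tMax, t + dt)
      break
    }
    if (t + dt >= tMax) break
    t <- t + dt
    idx <- sample.int(nAlive, 1L)
    who <- alive[idx]
    if (runif(1) < b / (b + d)) { # speciation: lineage splits in two
      if (nL + 2L > maxL) {
        maxL <- maxL * 2L
        length(parent) <- maxL; length(tBirth) <- maxL
        length(tEnd) <- maxL; length(status) <- maxL
        length(alive) <- maxL
      }
      kids <- nL + 1:2
      parent[kids] <- who; tBirth[kids] <- t; status[kids] <- 0L
      status[who] <- 2L; tEnd[who] <- t
      nL <- nL + 2L
      alive[idx] <- kids[1]
      nAlive <- nAlive + 1L
      alive[nAlive] <- kids[2]
    } else {
      status[who] <- 1L; tEnd[who] <- t
      alive[idx] <- alive[nAlive]
      nAlive <- nAlive - 1L
    }
  }
  alive <- alive[seq_len(nAlive)]
  if (length(alive) < 2L) {
    cond <- structure(class = c("lophiphy_extinct", "error", "condition"),
                      list(message = "birth-death process left < 2 extant lineages",
                           call = sys.call()))
    stop(cond)
  }
  tEnd[alive] <- tMax; status[alive] <- 0L
  children <- split(seq_len(nL), factor(parent[seq_len(nL)], levels = 0:nL))
  survives <- logical(nL)
  for (i in rev(seq_len(nL))) {
    survives[i] <- if (status[i] == 0L) TRUE
                   else if (status[i] == 2L) any(survives[children[[as.character(i)]]])
                   else FALSE
  }
  # reconstructed tree as Newick: follow surviving lineages, suppressing
  # pass-through (single-survivor) splits by extending the branch
  desc <- function(i, from) {
    repeat {
      if (status[i] == 0L)
        return(sprintf("t%d:%.10g", i, tMax - from))
      kids <- children[[as.character(i)]]
      kids <- kids[survives[kids]]
      if (length(kids) == 2L)
        return(sprintf("(%s,%s):%.10g", desc(kids[1], tEnd[i]),
                       desc(kids[2], tEnd[i]), tEnd[i] - from))
      i <- kids # single surviving child: extend through
    }
  }
  rootKids <- which(parent[seq_len(nL)] == 0L & survives[seq_len(nL)])
  nwk <- if (length(rootKids) == 2L)
    sprintf("(%s,%s);", desc(rootKids[1], 0), desc(rootKids[2], 0))
  else { # one crown lineage survived; its first surviving split is the root
    sub <- desc(rootKids, 0)
    sub <- sub("(:[0-9.eE+-]+)$", ";", sub)
    if (!grepl("\\);$", sub)) { # a single tip: cannot form a tree
      cond <- structure(class = c("lophiphy_extinct", "error", "condition"),
                        list(message = "only one extant lineage survived",
                             call = sys.call()))
      stop(cond)
    }
    sub
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "stemAge") <- tMax
  tree
}

#' Simulate autocorrelated rates by geometric Brownian motion
#'
#' The log substitution rate evolves by Brownian motion along the tree: for a
#' child node at time-distance \code{dt} below its parent,
#' \code{log r_child ~ Normal(log r_parent - correction, nu * dt)} with
#' \code{correction = nu*dt/2} when \code{meanCorrection = TRUE} (the
#' multidivtime convention that keeps the rate itself, not its log, centred)
#' and 0 otherwise.  The branch rate is the arithmetic mean of its two
#' endpoint node rates, and the substitution branch length is branch rate
#' times duration.
#'
#' @param tree rooted ultrametric \code{phylo} with branch lengths in Myr.
#' @param rootRate substitution rate at the root (subst/site/Myr), > 0.
#' @param nu Brownian variance of the log rate per Myr, >= 0.
#' @param seed integer seed.
#' @param meanCorrection subtract \code{nu*dt/2} from the child's expected
#'   log rate (default \code{FALSE}).
#' @return list with \code{nodeRates} (per ape node number),
#'   \code{branchRates} and \code{branchDurations} (per edge), and
#'   \code{substTree} (the tree with branch lengths in subst/site).
#' @export
simulateGBMRates <- function(tree, rootRate, nu, seed, meanCorrection = FALSE) {
  stopifnot(rootRate > 0, nu >= 0)
  if (any(tree$edge.length < 0)) stop("negative branch duration")
  set.seed(as.integer(seed))
  nTot <- ape::Ntip(tree) + tree$Nnode
  logr <- numeric(nTot)
  logr[.rootNode(tree)] <- log(rootRate)
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  for (i in rev(seq_len(nrow(edge)))) { # preorder traversal
    dt <- po$edge.length[i]
    mu <- logr[edge[i, 1]] - if (meanCorrection) nu * dt / 2 else 0
    logr[edge[i, 2]] <- rnorm(1, mu, sqrt(nu * dt))
  }
  nodeRates <- exp(logr)
  branchRates <- (nodeRates[tree$edge[, 1]] + nodeRates[tree$edge[, 2]]) / 2
  substTree <- tree
  substTree$edge.length <- branchRates * tree$edge.length
  list(nodeRates = nodeRates, branchRates = branchRates,
       branchDurations = tree$edge.length, substTree = substTree)
}

#' Simulate a partitioned alignment under GTR+Gamma / F84+Gamma
#'
#' Simulates each partition independently along the tree (branch lengths in
#' substitutions/site) from a stationary root draw, with discrete-gamma
#' among-site rate variation, then optionally blanks contiguous blocks per
#' taxon to mimic regions that failed sequencing.  Sequence evolution along
#' branches is delegated to \code{phangorn::simSeq}, one call per gamma
#' category.
#'
#' @param tree \code{phylo} with branch lengths in subst/site.
#' @param models named list of [SubstModel-class] (names become partition
#'   labels; must be valid partition labels) or a single model (labelled
#'   \code{codon1}).
#' @param lengths integer vector of sites per partition (same order/names as
#'   \code{models}).
#' @param seed integer seed.
#' @param missingBlocks optional data.frame with columns \code{taxon},
#'   \code{start}, \code{end} (1-based inclusive site range) to blank with
#'   \code{"?"}.
#' @return A [PartitionedAlignment-class].
#' @export
simulateAlignment <- function(tree, models, lengths, seed, missingBlocks = NULL) {
  if (is(models, "SubstModel")) models <- list(codon1 = models)
  if (length(lengths) != length(models)) stop("one length per partition model")
  if (any(lengths < 1)) stop("zero-length partition rejected")
  if (is.null(names(models)) || !all(names(models) %in% PARTITION_LEVELS))
    stop("models must be named by partition label")
  set.seed(as.integer(seed))
  blocks <- vector("list", length(models))
  for (pi in seq_along(models)) {
    model <- models[[pi]]
    L <- lengths[pi]
    rates <- discreteGammaRates(model@alpha, model@nCategories)
    cat4 <- sample.int(length(rates), L, replace = TRUE)
    cols <- matrix("", nrow = ape::Ntip(tree), ncol = L,
                   dimnames = list(tree$tip.label, NULL))
    exch <- if (model@model == "GTR") model@exch else {
      piR <- model@pi[1] + model@pi[3]; piY <- model@pi[2] + model@pi[4]
      c(1, 1 + model@kappa / piR, 1, 1, 1 + model@kappa / piY, 1)
    }
    for (ci in unique(cat4)) {
      idx <- which(cat4 == ci)
      sim <- phangorn::simSeq(tree, l = length(idx), Q = exch, bf = model@pi,
                              rate = rates[ci] * model@rate, type = "DNA")
      m <- toupper(as.character(sim))
      cols[rownames(m), idx] <- m
    }
    blocks[[pi]] <- cols
  }
  seqs <- do.call(cbind, blocks)
  partition <- rep(names(models), lengths)
  gene <- rep(paste0("sim_", names(models)), lengths)
  if (!is.null(missingBlocks)) {
    for (r in seq_len(nrow(missingBlocks))) {
      tx <- missingBlocks$taxon[r]
      seqs[tx, missingBlocks$start[r]:missingBlocks$end[r]] <- "?"
    }
  }
  partitionedAlignment(seqs, partition, gene)
}

#' Sample contiguous missing-data blocks
#'
#' Draws, for a subset of taxa, one contiguous site range each to blank,
#' emulating sequencing failures of whole regions rather than scattered
#' single-site dropout.
#'
#' @param taxa taxon names eligible for dropout.
#' @param nSites total alignment length.
#' @param nTaxaMissing how many taxa get a missing block.
#' @param blockFraction range (min, max) of the missing fraction per taxon.
#' @param seed integer seed.
#' @return data.frame(taxon, start, end) suitable for
#'   [simulateAlignment()]'s \code{missingBlocks}.
#' @export
sampleMissingBlocks <- function(taxa, nSites, nTaxaMissing = 1L,
                                blockFraction = c(0.2, 0.4), seed = 1L) {
  set.seed(as.integer(seed))
  chosen <- sample(taxa, nTaxaMissing)
  out <- lapply(chosen, function(tx) {
    len <- round(nSites * runif(1, blockFraction[1], blockFraction[2]))
    start <- sample.int(nSites - len + 1L, 1L)
    data.frame(taxon = tx, start = start, end = start + len - 1L)
  })
  do.call(rbind, out)
}

#' Simulate a k-state Mk1 trait on a tree
#'
#' Root state uniform over the k states; states then evolve along each
#' branch under the Mk1 model (single rate q between every pair of distinct
#' states).  With k = 4 this matches the male-attachment coding 0-3.
#'
#' @param tree \code{phylo} with branch lengths (any time-like scale
#'   consistent with q).
#' @param k number of states (default 4).
#' @param q Mk1 rate, >= 0.
#' @param seed integer seed.
#' @return named integer vector of tip states in \code{0:(k-1)}.
#' @export
simulateMkTrait <- function(tree, k = 4L, q, seed) {
  stopifnot(k >= 2L, q >= 0)
  set.seed(as.integer(seed))
  nTot <- ape::Ntip(tree) + tree$Nnode
  state <- integer(nTot)
  state[.rootNode(tree)] <- sample.int(k, 1L)
  edge <- stats::reorder(tree, "postorder")$edge
  elen <- stats::reorder(tree, "postorder")$edge.length
  for (i in rev(seq_len(nrow(edge)))) {
    P <- mkTransitionMatrix(mkModel(k, q), elen[i])
    state[edge[i, 2]] <- sample.int(k, 1L, prob = P[state[edge[i, 1]], ])
  }
  setNames(state[seq_len(ape::Ntip(tree))] - 1L, tree$tip.label)
}

#' Simulate a complete synthetic dataset
#'
#' Chains the generators into one reproducible object: birth-death
#' chronogram, geometric-Brownian rates, a partitioned alignment on the
#' resulting substitution tree, and an Mk trait.
#'
#' @param bd list(b, d, tMax, nTarget) for [simulateBDTree()].
#' @param gbm list(rootRate, nu) for [simulateGBMRates()].
#' @param models,lengths for [simulateAlignment()].
#' @param trait list(k, q) for [simulateMkTrait()].
#' @param missingBlocks passed to [simulateAlignment()].
#' @param seed integer master seed (stage seeds are derived from it).
#' @return list with \code{tree} (chronogram), \code{rates},
#'   \code{substTree}, \code{alignment}, \code{trait}, \code{seed}.
#' @export
simulateDataset <- function(bd, gbm, models, lengths, trait = list(k = 4L, q = 0.02),
                            missingBlocks = NULL, seed = 1L) {
  seed <- as.integer(seed)
  tree <- simulateBDTree(bd$b, bd$d, bd$tMax, bd$nTarget, seed = seed)
  rates <- simulateGBMRates(tree, gbm$rootRate, gbm$nu, seed = seed + 1L)
  aln <- simulateAlignment(rates$substTree, models, lengths, seed = seed + 2L,
                           missingBlocks = missingBlocks)
  tr <- simulateMkTrait(tree, trait$k, trait$q, seed = seed + 3L)
  list(tree = tree, rates = rates, substTree = rates$substTree,
       alignment = aln, trait = tr, seed = seed)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the alignment (FASTA), a partition table (TSV: gene, start, end,
#' class, codon_phase; 1-based inclusive), the chronogram and substitution
#' tree (Newick), the trait table (CSV) and a truth record (JSON with true
#' ages, node rates and the seed).
#'
#' @param ds a dataset from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSimulatedDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             partitions = file.path(dir, "partitions.tsv"),
             chronogram = file.path(dir, "chronogram.nwk"),
             substTree = file.path(dir, "subst_tree.nwk"),
             trait = file.path(dir, "trait.csv"),
             truth = file.path(dir, "truth.json"))
  writeAlignment(ds$alignment, paths["alignment"], format = "fasta")
  writePartitionTable(ds$alignment, paths["partitions"])
  ape::write.tree(ds$tree, paths["chronogram"])
  ape::write.tree(ds$substTree, paths["substTree"])
  write.table(data.frame(taxon = names(ds$trait), state = as.integer(ds$trait)),
              paths["trait"], sep = ",", row.names = FALSE, quote = FALSE)
  truth <- list(seed = ds$seed,
                nodeAges = as.list(setNames(nodeAges(ds$tree),
                                            seq_along(nodeAges(ds$tree)))),
                nodeRates = ds$rates$nodeRates,
                branchRates = ds$rates$branchRates)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
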