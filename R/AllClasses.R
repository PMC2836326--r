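#' @import methods
#' @importFrom stats dnorm pnorm qnorm qgamma pgamma rexp runif rnorm rgamma
#'   optimize optim rmultinom quantile setNames var sd
#' @importFrom utils read.delim write.table head tail
NULL

PARTITION_LEVELS <- c("codon1", "codon2", "codon3", "rRNA", "tRNA")

#' Partitioned multiple sequence alignment
#'
#' The central sequence container of the package: a site-by-taxon character
#' matrix over the DNA alphabet (IUPAC codes plus \code{"-"} and \code{"?"}),
#' with every site carrying exactly one partition label (first, second or
#' third codon position, rRNA or tRNA) and a gene name.  Gaps are treated as
#' missing data throughout.  Internally all site coordinates are 0-based
#' half-open; user-facing reports are 1-based inclusive.
#'
#' @slot seqs character matrix, rows = taxa (rownames set), cols = sites.
#' @slot partition character vector, one of \code{codon1, codon2, codon3,
#'   rRNA, tRNA} per site.
#' @slot gene character vector, gene name per site.
#'
#' @seealso [partitionedAlignment()], [ryRecode()], [excludeFrameOverlaps()]
#' @export
setClass("PartitionedAlignment",
  representation(seqs = "matrix", partition = "character", gene = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.character(object@seqs)) msg <- c(msg, "seqs must be a character matrix")
    if (is.null(rownames(object@seqs))) msg <- c(msg, "seqs must have taxon rownames")
    if (length(object@partition) != ncol(object@seqs))
      msg <- c(msg, "partition labels must match the number of sites")
    if (length(object@gene) != ncol(object@seqs))
      msg <- c(msg, "gene labels must match the number of sites")
    if (!all(object@partition %in% PARTITION_LEVELS))
      msg <- c(msg, sprintf("partition labels must be in {%s}",
                            paste(PARTITION_LEVELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a PartitionedAlignment
#'
#' @param seqs character matrix (taxa x sites) with taxon rownames; lower- or
#'   upper-case IUPAC nucleotide codes, \code{"-"} (gap, treated as missing)
#'   and \code{"?"} (missing).
#' @param partition character vector of per-site partition labels.
#' @param gene character vector of per-site gene names (defaults to a single
#'   anonymous gene).
#' @return A [PartitionedAlignment-class] object.
#' @examples
#' m <- rbind(t1 = c("A", "C", "G"), t2 = c("A", "T", "G"))
#' partitionedAlignment(m, c("codon1", "codon2", "codon3"))
#' @export
partitionedAlignment <- function(seqs, partition, gene = rep("gene1", ncol(seqs))) {
  seqs[] <- toupper(seqs)
  new("PartitionedAlignment", seqs = seqs, partition = as.character(partition),
      gene = as.character(gene))
}

#' @describeIn PartitionedAlignment-class taxon names
#' @param x,object a \code{PartitionedAlignment}
#' @export
alnTaxa <- function(x) rownames(x@seqs)

#' @describeIn PartitionedAlignment-class character matrix of the alignment
#' @export
alnMatrix <- function(x) x@seqs

#' @describeIn PartitionedAlignment-class per-site partition labels
#' @export
sitePartition <- function(x) x@partition

#' @describeIn PartitionedAlignment-class per-site gene labels
#' @export
siteGene <- function(x) x@gene

#' @describeIn PartitionedAlignment-class number of sites
#' @export
nSites <- function(x) ncol(x@seqs)

#' @describeIn PartitionedAlignment-class number of taxa
#' @export
nTaxa <- function(x) nrow(x@seqs)

setMethod("show", "PartitionedAlignment", function(object) {
  cat("PartitionedAlignment:", nTaxa(object), "taxa x", nSites(object), "sites\n")
  tab <- table(factor(object@partition, levels = PARTITION_LEVELS))
  cat("  partitions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(object@seqs %in% c("-", "?"))
  cat(sprintf("  missing/gap fraction: %.3f\n", miss))
})

#' Subset sites of a PartitionedAlignment
#'
#' @param x a \code{PartitionedAlignment}
#' @param i row (taxon) index
#' @param j column (site) index
#' @param ... ignored
#' @param drop ignored (always \code{FALSE})
#' @export
setMethod("[", "PartitionedAlignment", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@seqs))
  if (missing(j)) j <- seq_len(ncol(x@seqs))
  new("PartitionedAlignment", seqs = x@seqs[i, j, drop = FALSE],
      partition = x@partition[j], gene = x@gene[j])
})

#' Nucleotide substitution model (GTR+Gamma or F84+Gamma)
#'
#' Holds the parameters of a reversible nucleotide model with discrete-gamma
#' rate variation: either the general time-reversible model (six
#' exchangeabilities) or F84 (one transition/transversion parameter), base
#' frequencies, the gamma shape and the number of rate categories, plus a
#' partition-specific branch-length multiplier.
#'
#' @slot model \code{"GTR"} or \code{"F84"}.
#' @slot exch six exchangeabilities (order AC, AG, AT, CG, CT, GT; GTR only).
#' @slot kappa F84 transition/transversion parameter (F84 only).
#' @slot pi base frequencies (A, C, G, T), summing to one.
#' @slot alpha gamma shape; \code{Inf} means no rate variation.
#' @slot nCategories number of discrete gamma categories.
#' @slot rate branch-length multiplier for this partition.
#' @export
setClass("SubstModel",
  representation(model = "character", exch = "numeric", kappa = "numeric",
                 pi = "numeric", alpha = "numeric", nCategories = "integer",
                 rate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@model %in% c("GTR", "F84")) msg <- c(msg, "model must be GTR or F84")
    if (length(object@pi) != 4 || any(object@pi <= 0) ||
        abs(sum(object@pi) - 1) > 1e-8)
      msg <- c(msg, "pi must be 4 positive frequencies summing to 1")
    if (object@model == "GTR" && (length(object@exch) != 6 || any(object@exch <= 0)))
      msg <- c(msg, "GTR needs 6 positive exchangeabilities")
    if (object@model == "F84" && (length(object@kappa) != 1 || object@kappa < 0))
      msg <- c(msg, "F84 needs a single kappa >= 0")
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0 (use Inf for no variation)")
    if (object@nCategories < 1L) msg <- c(msg, "nCategories must be >= 1")
    if (object@rate <= 0) msg <- c(msg, "rate multiplier must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a substitution model
#'
#' @param model \code{"GTR"} or \code{"F84"}.
#' @param exch six GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param kappa F84 transition/transversion parameter.
#' @param pi base frequencies (A, C, G, T).
#' @param alpha gamma shape parameter (\code{Inf} = single rate).
#' @param nCategories number of discrete gamma categories (default 4).
#' @param rate branch-length multiplier for the partition (default 1).
#' @return A [SubstModel-class] object.
#' @examples
#' substModel("GTR", exch = c(1, 4, 1, 1, 4, 1), alpha = 0.5)
#' @export
substModel <- function(model = c("GTR", "F84"), exch = rep(1, 6), kappa = 2,
                       pi = rep(0.25, 4), alpha = Inf, nCategories = 4L,
                       rate = 1) {
  model <- match.arg(model)
  if (is.infinite(alpha)) nCategories <- 1L
  new("SubstModel", model = model, exch = exch, kappa = kappa, pi = pi / sum(pi),
      alpha = alpha, nCategories = as.integer(nCategories), rate = rate)
}

setMethod("show", "SubstModel", function(object) {
  cat(sprintf("SubstModel: %s+G(alpha=%s, %d categories), rate multiplier %.3g\n",
              object@model,
              if (is.infinite(object@alpha)) "Inf" else format(object@alpha),
              object@nCategories, object@rate))
  cat("  pi:", paste(sprintf("%.3f", object@pi), collapse = " "), "\n")
})

#' Per-site log-likelihood table
#'
#' A candidate-trees-by-sites matrix of per-site log-likelihoods, the input
#' to the RELL bootstrap and the AU topology test.  Row sums equal each
#' tree's total log-likelihood.
#'
#' @slot scores numeric matrix (trees x sites), rownames = tree labels.
#' @export
setClass("SiteLogLikTable",
  representation(scores = "matrix"),
  validity = function(object) {
    if (!is.numeric(object@scores)) return("scores must be numeric")
    if (is.null(rownames(object@scores))) return("scores must have tree rownames")
    TRUE
  })

#' Construct a per-site log-likelihood table
#'
#' @param scores numeric matrix, one row per candidate tree, one column per
#'   site; rownames label the trees.
#' @return A [SiteLogLikTable-class] object.
#' @export
siteLogLikTable <- function(scores) {
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("tree", seq_len(nrow(scores)))
  new("SiteLogLikTable", scores = scores)
}

#' @describeIn SiteLogLikTable-class the trees x sites score matrix
#' @param x a \code{SiteLogLikTable}
#' @export
siteScores <- function(x) x@scores

#' @describeIn SiteLogLikTable-class total log-likelihood per tree
#' @export
treeLogLik <- function(x) rowSums(x@scores)

setMethod("show", "SiteLogLikTable", function(object) {
  cat("SiteLogLikTable:", nrow(object@scores), "trees x", ncol(object@scores),
      "sites\n")
  tot <- rowSums(object@scores)
  cat("  total lnL:", paste(sprintf("%s=%.2f", names(tot), tot), collapse = ", "),
      "\n")
})

#' Mk1 discrete character model
#'
#' The k-state one-parameter Markov model (the k-state generalisation of
#' Jukes-Cantor): a single instantaneous rate \code{q} between every ordered
#' pair of distinct states.
#'
#' @slot k number of states.
#' @slot q instantaneous rate between each pair of distinct states.
#' @export
setClass("MkModel", representation(k = "integer", q = "numeric"),
  validity = function(object) {
    if (object@k < 2L) return("k must be >= 2")
    if (object@q < 0) return("q must be >= 0")
    TRUE
  })

#' Construct an Mk1 model
#' @param k number of states (default 4, the male-attachment coding 0-3).
#' @param q rate between each pair of distinct states.
#' @return An [MkModel-class] object.
#' @export
mkModel <- function(k = 4L, q = 0.1) new("MkModel", k = as.integer(k), q = q)

#' Marginal ancestral-state reconstruction
#'
#' Per-node normalised marginal likelihoods of each character state, the
#' fitted Mk1 model and the total log-likelihood.  Nodes whose two best
#' states differ by less than \code{equivocalMargin} are flagged equivocal.
#'
#' @slot probs numeric matrix (nodes x states), each row summing to one;
#'   rows are ordered as ape node numbers (tips first).
#' @slot model fitted [MkModel-class].
#' @slot logLik total log-likelihood at the fitted rate.
#' @slot equivocal logical per node.
#' @slot boundary TRUE if the rate was fitted at the q = 0 boundary.
#' @export
setClass("AncestralReconstruction",
  representation(probs = "matrix", model = "MkModel", logLik = "numeric",
                 equivocal = "logical", boundary = "logical"))

setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf("AncestralReconstruction: %d nodes x %d states, q = %.5g, lnL = %.4f\n",
              nrow(object@probs), ncol(object@probs), object@model@q, object@logLik))
  cat(sprintf("  equivocal nodes: %d\n", sum(object@equivocal)))
})

#' Posterior sample from the relaxed-clock dating MCMC
#'
#' Holds the retained MCMC samples of node ages (Myr), per-partition node
#' log-rates and Brownian variances, together with the chain settings, the
#' priors, the calibration constraints and per-node posterior summaries.
#'
#' @slot ages matrix of sampled internal-node ages (samples x nodes), columns
#'   named by ape node number.
#' @slot rates matrix of sampled node log-rates for the first partition.
#' @slot nu matrix of sampled Brownian variances (samples x partitions).
#' @slot summary data.frame: node, mean, lower and upper 95 percent credible
#'   limits.
#' @slot settings,priors lists of chain settings and prior parameters (Myr).
#' @slot constraints data.frame of node bounds actually enforced.
#' @slot seed integer seed of the chain.
#' @slot rhat split-Rhat of the root age across replicate chains (NA for a
#'   single chain).
#' @slot converged logical convergence flag (split-Rhat <= 1.1).
#' @export
setClass("ChronosPosterior",
  representation(ages = "matrix", rates = "matrix", nu = "matrix",
                 summary = "data.frame", settings = "list", priors = "list",
                 constraints = "data.frame", seed = "integer", rhat = "numeric",
                 converged = "logical"))

setMethod("show", "ChronosPosterior", function(object) {
  cat("ChronosPosterior:", nrow(object@ages), "samples,",
      ncol(object@ages), "internal nodes\n")
  root <- object@summary[1, ]
  cat(sprintf("  root age: %.1f Myr (95%% CI %.1f-%.1f)\n",
              root$mean, root$lower, root$upper))
  if (!is.na(object@rhat))
    cat(sprintf("  split-Rhat (root age): %.3f (%s)\n", object@rhat,
                if (object@converged) "converged" else "NOT converged"))
})

#' @describeIn ChronosPosterior-class per-node posterior age summary
#' @param x a \code{ChronosPosterior}
#' @export
ageSummary <- function(x) x@summary

#' @describeIn ChronosPosterior-class matrix of sampled internal-node ages
#' @export
ageSamples <- function(x) x@ages
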