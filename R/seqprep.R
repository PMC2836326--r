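# Dataset preparation: reading-frame overlap exclusion, RY-recoding of
# third codon positions, the three dataset variants, and log-diversity
# taxon subsampling for divergence dating.

DATASET_VARIANTS <- c("12n3rRTn", "123nRTn", "12nRTn")

#' Dataset variant descriptor
#'
#' Maps a variant name to its third-codon-position treatment:
#' \code{12n3rRTn} = RY-recode third positions, \code{123nRTn} = include all
#' positions unchanged, \code{12nRTn} = exclude third positions.
#'
#' @param name one of \code{"12n3rRTn"}, \code{"123nRTn"}, \code{"12nRTn"}.
#' @return list with \code{name} and \code{thirdPositionTreatment}.
#' @export
datasetVariant <- function(name = DATASET_VARIANTS) {
  name <- match.arg(name)
  list(name = name,
       thirdPositionTreatment = switch(name, "12n3rRTn" = "RY_recode",
                                       "123nRTn" = "include",
                                       "12nRTn" = "exclude"))
}

#' Remove duplicated columns created by overlapping reading frames
#'
#' Mitochondrial protein genes can share nucleotides across reading frames
#' (ATPase8/6, ND4L/4, ND5/6).  When each gene is aligned as its own block,
#' those shared nucleotides appear twice in the concatenated alignment.
#' Using the genomic coordinates in the annotation (\code{gstart},
#' \code{gend}), this drops the duplicated sites from the downstream gene's
#' block, so each shared position is kept once and attributed to the
#' upstream gene.  The alignment shortens by the total overlap.
#'
#' @param aln a [PartitionedAlignment-class].
#' @param annot annotation data.frame with columns \code{gene, start, end,
#'   class, codon_phase, gstart, gend} (defaults to
#'   \code{attr(aln, "annotation")}).
#' @return the trimmed [PartitionedAlignment-class].
#' @section Errors: a genomic position claimed by more than two genes is
#'   rejected with a diagnostic.
#' @export
excludeFrameOverlaps <- function(aln, annot = attr(aln, "annotation")) {
  if (is.null(annot) || is.null(annot$gstart))
    return(aln) # no genomic coordinates: nothing to detect
  cod <- annot[annot$class == "coding", , drop = FALSE]
  cover <- integer(max(cod$gend, 0))
  for (r in seq_len(nrow(cod))) {
    idx <- cod$gstart[r]:cod$gend[r]
    cover[idx] <- cover[idx] + 1L
  }
  if (any(cover > 2L))
    stop("genomic position(s) covered by more than two genes: ",
         paste(head(which(cover > 2L)), collapse = ", "))
  drop <- integer(0)
  if (nrow(cod) >= 2) {
    ord <- order(cod$gstart)
    cod <- cod[ord, , drop = FALSE]
    for (r in seq_len(nrow(cod) - 1)) {
      up <- cod[r, ]; down <- cod[r + 1, ]
      ovl <- up$gend - down$gstart + 1L
      if (ovl > 0) {
        # first ovl alignment columns of the downstream block duplicate the
        # last ovl of the upstream block
        drop <- c(drop, down$start:(down$start + ovl - 1L))
      }
    }
  }
  if (!length(drop)) return(aln)
  keep <- setdiff(seq_len(nSites(aln)), drop)
  out <- aln[, keep]
  attr(out, "annotation") <- NULL
  attr(out, "droppedSites") <- drop
  out
}

# RY map at third codon positions: purine-only codes -> A, pyrimidine-only
# codes -> C, everything else (incl. gaps) -> missing '?'
.RY_MAP <- c(A = "A", G = "A", R = "A", C = "C", T = "C", U = "C", Y = "C")

#' RY-recode third codon positions (dataset variants)
#'
#' For the \code{12n3rRTn} variant, third-codon-position purines (A/G and
#' the ambiguity code R) are recoded to \code{A} and pyrimidines (C/T/Y) to
#' \code{C}, so only transversions carry signal there; every other symbol at
#' a third position (N, S, W, K, M, gaps, ...) becomes missing \code{"?"},
#' since RY-coding retains no information about it.  \code{12nRTn} drops the
#' third-position sites entirely and \code{123nRTn} is the identity.  All
#' taxa are recoded alike.  Other partitions are never touched, and the
#' operation is idempotent.
#'
#' @param aln a [PartitionedAlignment-class].
#' @param variant a variant name or [datasetVariant()] result.
#' @return the transformed [PartitionedAlignment-class].
#' @examples
#' m <- rbind(t1 = c("A", "A"), t2 = c("G", "G"))
#' aln <- partitionedAlignment(m, c("codon1", "codon3"))
#' alnMatrix(ryRecode(aln, "12n3rRTn"))
#' @export
ryRecode <- function(aln, variant = "12n3rRTn") {
  if (is.character(variant)) variant <- datasetVariant(variant)
  third <- sitePartition(aln) == "codon3"
  switch(variant$thirdPositionTreatment,
    include = aln,
    exclude = aln[, !third],
    RY_recode = {
      m <- alnMatrix(aln)
      sub <- m[, third, drop = FALSE]
      mapped <- .RY_MAP[sub]
      mapped[is.na(mapped)] <- "?"
      m[, third] <- mapped
      partitionedAlignment(m, sitePartition(aln), siteGene(aln))
    })
}

#' Allocate dating slots in proportion to log species diversity
#'
#' Distributes \code{totalSlots} taxon slots across clades proportionally to
#' \code{log10} of each clade's described species diversity, with a floor of
#' two slots per clade and largest-remainder rounding.  Used to thin densely
#' sampled clades before divergence dating (mitigating the node-density
#' effect).
#'
#' @param speciesTotal named numeric vector: described species per clade.
#' @param totalSlots total number of taxa to retain (>= 2 per clade).
#' @return named integer vector of slots per clade, summing to
#'   \code{totalSlots}.
#' @export
allocateSlotsByLogDiversity <- function(speciesTotal, totalSlots) {
  g <- length(speciesTotal)
  if (totalSlots < 2L * g)
    stop("totalSlots must be at least 2 per clade (", 2L * g, ")")
  w <- log10(pmax(speciesTotal, 1))
  if (sum(w) == 0) w <- rep(1, g)
  raw <- totalSlots * w / sum(w)
  base <- pmax(2L, floor(raw))
  leftover <- totalSlots - sum(base)
  if (leftover < 0) { # floors exceeded the budget: trim the smallest raws
    ord <- order(raw)
    i <- 1L
    while (leftover < 0) {
      if (base[ord[i]] > 2L) { base[ord[i]] <- base[ord[i]] - 1L; leftover <- leftover + 1L }
      i <- if (i == g) 1L else i + 1L
    }
  } else if (leftover > 0) {
    rem <- raw - floor(raw)
    rem[base > floor(raw)] <- -Inf # clamped-up clades already got extra
    ord <- order(rem, decreasing = TRUE)
    take <- ord[seq_len(leftover)]
    base[take] <- base[take] + 1L
  }
  setNames(as.integer(base), names(speciesTotal))
}

#' Greedy maximum-phylogenetic-diversity taxon selection
#'
#' Selects \code{nSelect} tips maximising the summed branch length of the
#' induced subtree: the first two tips are the most distant pair, then each
#' further tip maximises the gain in phylogenetic diversity.  On trees this
#' greedy procedure attains the optimal PD subset.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param tips candidate tip labels (default all).
#' @param nSelect number of tips to keep.
#' @return character vector of selected tip labels.
#' @export
selectMaxPDTips <- function(tree, tips = tree$tip.label, nSelect) {
  stopifnot(nSelect >= 1, nSelect <= length(tips))
  if (nSelect == 1) return(tips[1])
  D <- ape::cophenetic.phylo(tree)[tips, tips, drop = FALSE]
  pick <- which(D == max(D), arr.ind = TRUE)[1, ]
  sel <- tips[pick]
  while (length(sel) < nSelect) {
    rest <- setdiff(tips, sel)
    gain <- vapply(rest, function(tx) .subtreePD(tree, c(sel, tx)), numeric(1))
    sel <- c(sel, rest[which.max(gain)])
  }
  sel
}

#' Subsample taxa per clade by log diversity and phylogenetic diversity
#'
#' Combines [allocateSlotsByLogDiversity()] with per-clade greedy max-PD
#' selection: slots go to clades in proportion to the log of their species
#' diversity (floor two), and within each clade the most distantly related
#' sampled taxa fill them.
#'
#' @param diversity data.frame with columns \code{clade} and
#'   \code{species_total}.
#' @param groups named character vector mapping each candidate tip label to
#'   its clade.
#' @param totalSlots total taxa to keep.
#' @param tree \code{phylo} containing all candidate tips.
#' @return list with \code{allocation} (slots per clade) and \code{taxa}
#'   (selected tip labels).
#' @export
subsampleByLogDiversity <- function(diversity, groups, totalSlots, tree) {
  st <- setNames(diversity$species_total, diversity$clade)
  alloc <- allocateSlotsByLogDiversity(st, totalSlots)
  sel <- character(0)
  for (cl in names(alloc)) {
    members <- names(groups)[groups == cl]
    if (!length(members)) stop("no sampled taxa for clade ", cl)
    k <- min(alloc[[cl]], length(members))
    sel <- c(sel, selectMaxPDTips(tree, members, k))
  }
  list(allocation = alloc, taxa = sel)
}
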