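# Alignment and annotation I/O.  Sequence formats go through ape (FASTA,
# sequential/interleaved PHYLIP, NEXUS); partition and annotation tables are
# plain TSV with 1-based inclusive coordinates at the file boundary.

.matrixFromApe <- function(x) {
  if (inherits(x, "DNAbin")) x <- as.character(as.matrix(x))
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1) stop("sequences are not aligned (unequal lengths)")
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  x[] <- toupper(x)
  x
}

#' Read an aligned sequence file
#'
#' @param file path to the alignment.
#' @param format \code{"fasta"}, \code{"phylip"} (sequential) or
#'   \code{"nexus"}.
#' @return character matrix (taxa x sites) with taxon rownames.
#' @export
readAlignmentMatrix <- function(file, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  x <- switch(format,
    fasta = ape::read.FASTA(file),
    phylip = ape::read.dna(file, format = "sequential"),
    nexus = ape::read.nexus.data(file))
  .matrixFromApe(x)
}

#' Read a partitioned alignment (alignment + annotation table)
#'
#' The annotation table is a TSV with columns \code{gene, start, end, class,
#' codon_phase} (and optionally \code{gstart, gend} genomic coordinates used
#' for reading-frame overlap detection).  \code{start}/\code{end} are 1-based
#' inclusive alignment coordinates; \code{class} is one of \code{coding},
#' \code{rRNA}, \code{tRNA}; \code{codon_phase} (1, 2 or 3) is the codon
#' position of the first site of a coding block.
#'
#' @param alnFile alignment path.
#' @param annotFile annotation TSV path.
#' @param format alignment format, as in [readAlignmentMatrix()].
#' @return A [PartitionedAlignment-class]; the annotation (with any genomic
#'   coordinates) is kept in \code{attr(, "annotation")}.
#' @export
readPartitionedAlignment <- function(alnFile, annotFile,
                                     format = c("fasta", "phylip", "nexus")) {
  m <- readAlignmentMatrix(alnFile, match.arg(format))
  annot <- read.delim(annotFile, stringsAsFactors = FALSE)
  lab <- .labelsFromAnnotation(ncol(m), annot)
  out <- partitionedAlignment(m, lab$partition, lab$gene)
  attr(out, "annotation") <- annot
  out
}

# Expand an annotation table into per-site partition and gene labels.
.labelsFromAnnotation <- function(nSites, annot) {
  partition <- rep(NA_character_, nSites)
  gene <- rep(NA_character_, nSites)
  for (r in seq_len(nrow(annot))) {
    idx <- annot$start[r]:annot$end[r]
    if (any(idx < 1 | idx > nSites)) stop("annotation outside alignment: ", annot$gene[r])
    if (any(!is.na(partition[idx])))
      stop("annotation blocks overlap in alignment coordinates: ", annot$gene[r])
    gene[idx] <- annot$gene[r]
    partition[idx] <- if (annot$class[r] == "coding") {
      # standard triplet cycling from the block's starting phase
      phase0 <- annot$codon_phase[r] - 1L
      paste0("codon", ((seq_along(idx) - 1L + phase0) %% 3L) + 1L)
    } else annot$class[r]  # rRNA, tRNA, or a uniform codon1/codon2/codon3 block
  }
  if (any(is.na(partition))) stop("annotation does not cover every site")
  list(partition = partition, gene = gene)
}

#' Write an alignment
#'
#' @param aln a [PartitionedAlignment-class] (or character matrix).
#' @param file output path.
#' @param format \code{"fasta"}, \code{"phylip"} or \code{"nexus"}.
#' @return invisibly, \code{file}.
#' @export
writeAlignment <- function(aln, file, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  m <- if (is(aln, "PartitionedAlignment")) alnMatrix(aln) else aln
  m[] <- tolower(m)
  if (format == "nexus") {
    ape::write.nexus.data(split(m, row(m)) |> setNames(rownames(m)) |>
                            lapply(as.character),
                          file, interleaved = FALSE)
  } else {
    bin <- ape::as.DNAbin(m)
    ape::write.dna(bin, file,
                   format = if (format == "fasta") "fasta" else "sequential",
                   colsep = "", nbcol = -1)
  }
  invisible(file)
}

#' Write the per-site partition map of an alignment
#'
#' Emits contiguous runs of (gene, partition) as a TSV with 1-based inclusive
#' coordinates: columns \code{gene, start, end, class, codon_phase}, the same
#' layout [readPartitionedAlignment()] consumes.
#'
#' @param aln a [PartitionedAlignment-class].
#' @param file output TSV path.
#' @return invisibly, \code{file}.
#' @export
writePartitionTable <- function(aln, file) {
  p <- sitePartition(aln); g <- siteGene(aln)
  isCodon <- grepl("^codon", p)
  blockKey <- cumsum(c(TRUE, g[-1] != g[-length(g)] |
                         (!isCodon[-1] & p[-1] != p[-length(p)])))
  rows <- lapply(split(seq_along(p), blockKey), function(idx) {
    if (!isCodon[idx[1]])
      return(data.frame(gene = g[idx[1]], start = idx[1],
                        end = idx[length(idx)], class = p[idx[1]],
                        codon_phase = NA_integer_))
    phase0 <- as.integer(sub("codon", "", p[idx[1]]))
    cycling <- paste0("codon", ((seq_along(idx) - 1L + phase0 - 1L) %% 3L) + 1L)
    if (identical(p[idx], cycling)) {
      # a standard triplet-cycling coding block
      data.frame(gene = g[idx[1]], start = idx[1], end = idx[length(idx)],
                 class = "coding", codon_phase = phase0)
    } else {
      # uniform single-position runs (e.g. simulated per-position blocks)
      runKey <- cumsum(c(TRUE, p[idx][-1] != p[idx][-length(idx)]))
      do.call(rbind, lapply(split(idx, runKey), function(ii)
        data.frame(gene = g[ii[1]], start = ii[1], end = ii[length(ii)],
                   class = p[ii[1]], codon_phase = NA_integer_)))
    }
  })
  write.table(do.call(rbind, rows), file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' Write a machine-readable partition map (JSON)
#'
#' @param aln a [PartitionedAlignment-class].
#' @param file output JSON path.
#' @return invisibly, \code{file}.
#' @export
writePartitionJSON <- function(aln, file) {
  p <- sitePartition(aln)
  sites <- lapply(setNames(nm = unique(p)), function(lv) which(p == lv))
  jsonlite::write_json(list(nSites = nSites(aln), taxa = alnTaxa(aln),
                            partitionSites = sites),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a trait table (taxon, state)
#'
#' @param file CSV with columns \code{taxon} and \code{state}; empty or NA
#'   states are treated as missing.
#' @return named integer vector (NA = missing).
#' @export
readTraitTable <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  setNames(suppressWarnings(as.integer(df$state)), df$taxon)
}

#' Read a calibration-constraint table
#'
#' CSV with columns \code{node} (label), \code{taxa} (semicolon-separated
#' tip names identifying the node as their MRCA; may be empty when
#' \code{node} is used directly), \code{lower}, \code{upper} (Myr; empty =
#' unbounded).
#'
#' @param file CSV path.
#' @return data.frame with columns node, taxa, lower, upper.
#' @export
readConstraints <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (is.null(df$taxa)) df$taxa <- ""
  df$lower <- suppressWarnings(as.numeric(df$lower))
  df$upper <- suppressWarnings(as.numeric(df$upper))
  bad <- !is.na(df$lower) & !is.na(df$upper) & df$lower > df$upper
  if (any(bad)) stop("constraint with lower > upper: ", paste(df$node[bad], collapse = ", "))
  df
}
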