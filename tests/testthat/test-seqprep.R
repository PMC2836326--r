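# A tiny annotated "mitogenome-like" fixture: three coding blocks, an rRNA
# and a tRNA block, with genomic coordinates that make gene pairs overlap.
makePrepFixture <- function(overlaps = c(10L, 7L, 7L)) {
  lens <- c(geneA = 30L, geneB = 30L, geneC = 21L, rrnS = 12L, trnF = 9L)
  # genomic layout: geneB starts inside geneA, geneC inside geneB
  gstart <- c(1L, 31L - overlaps[1], NA, NA, NA)
  gstart[3] <- gstart[2] + 30L - overlaps[2]
  gend <- c(30L, gstart[2] + 29L, gstart[3] + 20L, NA, NA)
  start <- cumsum(c(1L, head(lens, -1)))
  annot <- data.frame(gene = names(lens), start = start,
                      end = start + lens - 1L,
                      class = c("coding", "coding", "coding", "rRNA", "tRNA"),
                      codon_phase = c(1L, 1L, 1L, NA, NA),
                      gstart = gstart, gend = gend)
  set.seed(99)
  m <- matrix(sample(c("A", "C", "G", "T"), 4 * sum(lens), replace = TRUE),
              nrow = 4, dimnames = list(paste0("t", 1:4), NULL))
  lab <- lophiphy:::.labelsFromAnnotation(sum(lens), annot)
  aln <- partitionedAlignment(m, lab$partition, lab$gene)
  attr(aln, "annotation") <- annot
  aln
}

test_that("frame-overlap exclusion drops the duplicated downstream columns", {
  aln <- makePrepFixture(c(10L, 7L, 7L))
  out <- excludeFrameOverlaps(aln)
  expect_equal(nSites(out), nSites(aln) - 17L)
  # the upstream copies survive with their gene attribution intact
  expect_equal(sum(siteGene(out) == "geneA"), 30L)
  expect_equal(sum(siteGene(out) == "geneB"), 30L - 10L)
  expect_equal(sum(siteGene(out) == "geneC"), 21L - 7L)
  # non-coding partitions untouched
  expect_equal(sum(sitePartition(out) == "rRNA"), 12L)
  expect_equal(sum(sitePartition(out) == "tRNA"), 9L)
})

test_that("no overlaps means the identity transform", {
  aln <- makePrepFixture(c(0L, 0L, 0L))
  out <- excludeFrameOverlaps(aln)
  expect_identical(alnMatrix(out), alnMatrix(aln))
})

test_that("a position claimed by three genes is rejected", {
  aln <- makePrepFixture()
  annot <- attr(aln, "annotation")
  annot$gstart[3] <- 5L  # geneC now overlaps both geneA and geneB everywhere
  annot$gend[3] <- 25L
  expect_error(excludeFrameOverlaps(aln, annot), "more than two genes")
})

test_that("RY recoding maps third positions as stated and only there", {
  m <- rbind(t1 = c("A", "A", "A"), t2 = c("G", "G", "G"),
             t3 = c("C", "C", "C"), t4 = c("T", "T", "T"))
  aln <- partitionedAlignment(m, c("codon1", "codon2", "codon3"))
  out <- ryRecode(aln, "12n3rRTn")
  expect_equal(unname(alnMatrix(out)[, 3]), c("A", "A", "C", "C"))
  expect_equal(alnMatrix(out)[, 1:2], m[, 1:2])
  # ambiguity handling: R/Y keep their residual signal, the rest is missing
  m2 <- rbind(t1 = c("R", "Y", "N", "-", "?", "S"))
  aln2 <- partitionedAlignment(m2, rep("codon3", 6))
  expect_equal(unname(alnMatrix(ryRecode(aln2, "12n3rRTn"))[1, ]),
               c("A", "C", "?", "?", "?", "?"))
})

test_that("the three dataset variants relate as expected and recoding is idempotent", {
  tr <- simulateBDTree(0.1, 0, 25, nTarget = 5, seed = 31)
  models <- list(codon1 = substModel("GTR"), codon2 = substModel("GTR"),
                 codon3 = substModel("GTR"), tRNA = substModel("GTR"))
  aln <- simulateAlignment(tr, models, c(40, 40, 40, 30), seed = 32)
  ry <- ryRecode(aln, "12n3rRTn")
  all3 <- ryRecode(aln, "123nRTn")
  no3 <- ryRecode(aln, "12nRTn")
  expect_identical(alnMatrix(all3), alnMatrix(aln))
  expect_equal(nSites(no3), nSites(aln) - sum(sitePartition(aln) == "codon3"))
  expect_identical(alnMatrix(ryRecode(ry, "12n3rRTn")), alnMatrix(ry))
  expect_true(all(alnMatrix(ry)[, sitePartition(ry) == "codon3"] %in%
                    c("A", "C", "?")))
  # partition labels survive every transform except explicit removal
  expect_identical(sitePartition(ry), sitePartition(aln))
  expect_identical(sitePartition(no3),
                   sitePartition(aln)[sitePartition(aln) != "codon3"])
})

test_that("alignment formats round-trip exactly", {
  tr <- simulateBDTree(0.1, 0, 25, nTarget = 5, seed = 33)
  aln <- simulateAlignment(tr, substModel("GTR"), 50, seed = 34)
  m <- alnMatrix(aln)
  m[2, 5:9] <- "?"
  for (fmt in c("fasta", "phylip", "nexus")) {
    f <- withr::local_tempfile()
    writeAlignment(m, f, fmt)
    back <- readAlignmentMatrix(f, fmt)
    expect_identical(unname(back[rownames(m), ]), unname(m), label = fmt)
  }
})

test_that("slot allocation reproduces the realised suborder split from diversity totals", {
  div <- read.csv(system.file("extdata", "table1_diversity.csv",
                              package = "lophiphy"))
  totals <- tapply(div$species_total, div$suborder, sum)
  alloc <- allocateSlotsByLogDiversity(totals, 11L)
  expect_equal(sum(alloc), 11L)
  expect_equal(unname(alloc[["Ceratioidei"]]), 3L)
  expect_true(all(alloc[setdiff(names(alloc), "Ceratioidei")] == 2L))
  # symmetry: equal diversities share slots equally
  expect_true(all(allocateSlotsByLogDiversity(c(a = 50, b = 50), 6L) == 3L))
  expect_error(allocateSlotsByLogDiversity(c(a = 10, b = 10), 3L), "at least 2")
})

test_that("greedy max-PD selection equals exhaustive search on small trees", {
  for (seed in 1:6) {
    set.seed(seed)
    tr <- ape::rtree(9)
    k <- sample(3:5, 1)
    greedy <- selectMaxPDTips(tr, nSelect = k)
    combos <- utils::combn(tr$tip.label, k, simplify = FALSE)
    pds <- vapply(combos, function(s) lophiphy:::.subtreePD(tr, s), numeric(1))
    expect_equal(lophiphy:::.subtreePD(tr, greedy), max(pds),
                 tolerance = 1e-12)
  }
})

test_that("per-clade subsampling combines allocation with max-PD choice", {
  set.seed(7)
  tr <- ape::rtree(12)
  groups <- setNames(rep(c("big", "small"), each = 6), tr$tip.label)
  div <- data.frame(clade = c("big", "small"), species_total = c(1000, 10))
  res <- subsampleByLogDiversity(div, groups, 7L, tr)
  expect_equal(sum(res$allocation), 7L)
  expect_gt(res$allocation[["big"]], res$allocation[["small"]])
  expect_equal(length(res$taxa), 7L)
  expect_true(all(table(groups[res$taxa]) == res$allocation[names(table(groups[res$taxa]))]))
})
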