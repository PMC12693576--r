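mkAln <- function(ingroup, ancestor) {
  CodonAlignment(Biostrings::DNAStringSet(ingroup),
                 Biostrings::DNAStringSet(c(anc = ancestor)))
}

test_that("single-codon changes classify against the codon table", {
  # fixed synonymous: all ingroup AAA (Lys) vs ancestor AAG (Lys)
  ch <- tabulateChanges(mkAln(c(a = "AAA", b = "AAA", c = "AAA"), "AAG"))
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$kind, "fixed")
  expect_equal(ch$syn, 1); expect_equal(ch$nonsyn, 0)

  # polymorphic nonsynonymous at frequency 0.10 (AAA Lys / AAC Asn)
  ing <- setNames(c(rep("AAA", 9), "AAC"), paste0("s", 1:10))
  ch2 <- tabulateChanges(mkAln(ing, "AAA"))
  expect_identical(ch2$kind, "polymorphic")
  expect_equal(ch2$nonsyn, 1); expect_equal(ch2$syn, 0)
  expect_equal(ch2$maf, 0.1)

  # no changes when the ingroup matches the ancestor
  expect_identical(nrow(tabulateChanges(mkAln(c(a = "AAA", b = "AAA"), "AAA"))),
                   0L)
})

test_that("multi-step codon differences average over stop-free pathways", {
  # CCC (Pro) -> CAA (Gln): paths via CAC (His, 2 nonsyn) and CCA (Pro,
  # 1 syn + 1 nonsyn); equal weights give syn 0.5 / nonsyn 1.5
  ch <- tabulateChanges(mkAln(c(a = "CAA", b = "CAA"), "CCC"))
  expect_equal(ch$syn, 0.5)
  expect_equal(ch$nonsyn, 1.5)

  # TGG (Trp) -> TAT (Tyr): the path through TAG (stop) is excluded,
  # leaving only TGG -> TGT -> TAT, two nonsynonymous steps
  ch2 <- tabulateChanges(mkAln(c(a = "TAT", b = "TAT"), "TGG"))
  expect_equal(ch2$syn, 0)
  expect_equal(ch2$nonsyn, 2)
})

test_that("gap and stop codons are excluded with bookkeeping", {
  ch <- tabulateChanges(mkAln(c(a = "---AAA", b = "AAAAAA"), "AAAAAG"))
  expect_identical(attr(ch, "excluded"), 1L)   # the gapped column
  expect_identical(nrow(ch), 1L)               # the clean fixed syn column
  expect_warning(
    ch2 <- tabulateChanges(mkAln(c(a = "TAA", b = "AAA"), "AAA")),
    "stop codon")
  expect_identical(nrow(ch2), 0L)
  expect_error(mkAln(c(a = "AAA", b = "AAA"), "TAA"), "stop")
})

test_that("the frequency filter is strict at the cutoff and monotone", {
  ing <- setNames(c(rep("AAA", 45), rep("AAC", 5)), paste0("s", 1:50))
  # maf 0.10 removed at cutoff 0.12; maf 0.12 retained
  ch10 <- tabulateChanges(mkAln(ing, "AAA"))
  expect_identical(nrow(applyFrequencyFilter(ch10, 0.12)), 0L)
  ing12 <- setNames(c(rep("AAA", 44), rep("AAC", 6)), paste0("s", 1:50))
  ch12 <- tabulateChanges(mkAln(ing12, "AAA"))
  expect_identical(nrow(applyFrequencyFilter(ch12, 0.12)), 1L)
  # cutoff 0 is the identity
  expect_identical(nrow(applyFrequencyFilter(ch10, 0)), nrow(ch10))
  # raising the cutoff never increases Pn or Ps
  sim <- simulateCodonSet(100, 20,
    planted = list(polyNonsyn = c(0.05, 0.1, 0.25, 0.5),
                   polySyn = c(0.05, 0.15, 0.3)), seed = 5)
  ch <- tabulateChanges(sim$alignment)
  prev <- c(Inf, Inf)
  for (cut in c(0, 0.06, 0.12, 0.2, 0.4)) {
    r <- buildMKT(applyFrequencyFilter(ch, cut))
    now <- unname(mktCounts(r)[c("Pn", "Ps")])
    expect_true(all(now <= prev))
    prev <- now
  }
})

test_that("the 2x2 table, NI, alpha and conventions are computed correctly", {
  sim <- simulateCodonSet(80, 10,
    planted = list(fixedNonsyn = 5, fixedSyn = 10,
                   polyNonsyn = rep(0.5, 4), polySyn = rep(0.5, 8)),
    seed = 51)
  r <- mktTest(sim$alignment, cutoff = 0)
  expect_equal(unname(mktCounts(r)), c(5, 10, 4, 8))
  expect_equal(neutralityIndex(r), (4 / 8) / (5 / 10))
  expect_equal(mktAlpha(r), 0)

  # strong-selection arithmetic: (20,5,2,10) -> alpha = 1 - (0.2)/(4) = 0.95
  sim2 <- simulateCodonSet(80, 10,
    planted = list(fixedNonsyn = 20, fixedSyn = 5,
                   polyNonsyn = rep(0.5, 2), polySyn = rep(0.5, 10)),
    seed = 52)
  r2 <- mktTest(sim2$alignment, cutoff = 0)
  expect_equal(mktAlpha(r2), 0.95)

  empty <- simulateCodonSet(30, 6, planted = list(), seed = 53)
  r3 <- mktTest(empty$alignment)
  expect_equal(pValue(r3), 1)
  expect_true(is.na(neutralityIndex(r3)))
  expect_true(is.na(mktAlpha(r3)))
})

test_that("the two-tailed Fisher test matches enumeration and base R", {
  expect_equal(fisherTwoTailed(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisherTwoTailed(matrix(c(0, 5, 5, 0), 2)), 2 / 252)
  expect_error(fisherTwoTailed(matrix(c(-1, 1, 1, 1), 2)), "negative")
  set.seed(6)
  for (i in 1:100) {
    tab <- matrix(rpois(4, sample(1:12, 1)), 2)
    expect_equal(fisherTwoTailed(tab), fisherOracle(tab), tolerance = 1e-12)
    expect_equal(fisherTwoTailed(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the parsimony fallback reconstructs simple ancestors", {
  ing <- Biostrings::DNAStringSet(c(a = "AAAT", b = "AAAT", c = "AAGT"))
  # consensus AAAT; sister differs at site 3, outgroup agrees with sister
  anc <- inferAncestorParsimony(ing, "AAGT", "AAGT")
  expect_identical(anc$ancestor, "AAGT")
  expect_identical(anc$nUnresolved, 0L)
  # irreconcilable site masked with N
  anc2 <- inferAncestorParsimony(ing, "AACT", "AAGT")
  expect_identical(substr(anc2$ancestor, 3, 3), "N")
  expect_identical(anc2$nUnresolved, 1L)
})

test_that("role-tagged codon alignments load from FASTA", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "AAATTT", ">s2", "AAATTT",
               ">ancestor", "AAATTA", ">outgroup role=outgroup", "AAATTA"),
             path)
  aln <- readCodonAlignment(path)
  expect_identical(length(aln@ingroup), 2L)
  expect_identical(length(aln@outgroup), 1L)
  ch <- tabulateChanges(aln)
  expect_identical(ch$kind, "fixed")
})
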