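test_that("an event-free clade conserves every gene and the gene order", {
  ref <- forgeReference(nGenes = 20, nContigs = 2, seed = 31)
  phylo <- PhylogenyConfig("reference",
                           c(reference = 0, a = 5, b = 15, c = 30, d = 45))
  forged <- suppressMessages(forgeClade(ref, phylo, seed = 31))
  expect_identical(sort(names(forged$genomes)), c("a", "b", "c", "d"))
  expect_true(all(forged$truth$event == "conserved"))
  for (sp in names(forged$genomes)) {
    g <- forged$genomes[[sp]]
    expect_identical(length(genes(g)), 20L)
    expect_identical(sub(paste0(sp, "_"), "", geneIds(g)), geneIds(ref))
  }
})

test_that("a planted loss excises the gene and leaves the flanks adjacent", {
  ref <- forgeReference(nGenes = 10, nContigs = 1, seed = 32)
  phylo <- PhylogenyConfig("reference", c(reference = 0, sp = 10))
  ev <- data.frame(gene_id = "g005", species_id = "sp", event = "lost")
  forged <- suppressMessages(forgeClade(ref, phylo, events = ev, seed = 32))
  g <- forged$genomes$sp
  expect_false("sp_g005" %in% geneIds(g))
  ids <- geneIds(g)
  expect_identical(which(ids == "sp_g006") - which(ids == "sp_g004"), 1L)
  expect_identical(forged$truth$expected_call[
    forged$truth$gene_id == "g005"], "ABSENT_SYNTENY")
})

test_that("forging is byte-identical under the same seed", {
  ref <- forgeReference(nGenes = 8, nContigs = 1, seed = 33)
  phylo <- PhylogenyConfig("reference", c(reference = 0, sp = 25))
  f1 <- suppressMessages(forgeClade(ref, phylo, seed = 99))
  f2 <- suppressMessages(forgeClade(ref, phylo, seed = 99))
  expect_identical(as.character(contigs(f1$genomes$sp)),
                   as.character(contigs(f2$genomes$sp)))
  expect_identical(f1$truth, f2$truth)
  f3 <- suppressMessages(forgeClade(ref, phylo, seed = 100))
  expect_false(identical(as.character(contigs(f1$genomes$sp)),
                         as.character(contigs(f3$genomes$sp))))
})

test_that("an un-testable divergence regime is refused", {
  ref <- forgeReference(nGenes = 6, nContigs = 1, seed = 34)
  phylo <- PhylogenyConfig("reference", c(reference = 0, sp = 70))
  expect_error(
    suppressMessages(forgeClade(ref, phylo,
                                divergence = list(aaRatePerMy = 0.05),
                                seed = 1)),
    "below 0.05")
})

test_that("realized protein identity tracks the divergence model", {
  ref <- forgeReference(nGenes = 12, nContigs = 1, seed = 35)
  phylo <- PhylogenyConfig("reference", c(reference = 0, sp = 50))
  forged <- suppressMessages(forgeClade(ref, phylo, seed = 35))
  tgt <- forged$genomes$sp
  ids <- mapply(function(g) {
    al <- alignLocal(as.character(proteome(ref)[[g]]),
                     as.character(proteome(tgt)[[paste0("sp_", g)]]))
    al$identity
  }, geneIds(ref))
  expect_gt(mean(ids), exp(-0.002 * 50) - 0.05)
  expect_lt(mean(ids), exp(-0.002 * 50) + 0.05)
})

test_that("fertility simulation honours sterility, seeds and bad input", {
  fd <- simulateFertility(list(wildtype = list(mean = 50, dispersion = 5),
                               null = "sterile"), n = 20, seed = 7)
  expect_identical(nrow(fd), 40L)
  expect_true(all(fd$progeny[fd$genotype == "null"] == 0L))
  expect_true(all(fd$progeny >= 0))
  fd2 <- simulateFertility(list(wildtype = list(mean = 50, dispersion = 5),
                                null = "sterile"), n = 20, seed = 7)
  expect_identical(fd, fd2)
  zero <- simulateFertility(list(a = list(mean = 0, dispersion = 2),
                                 b = list(mean = 5, dispersion = 2)),
                            n = 5, seed = 1)
  expect_true(all(zero$progeny[zero$genotype == "a"] == 0L))
  expect_error(simulateFertility(list(a = list(mean = 5, dispersion = 0),
                                      b = "sterile"), n = 5, seed = 1),
               "dispersion")
  expect_error(simulateFertility(list(a = "sterile", b = "sterile"),
                                 n = 1, seed = 1), "n >= 2")
})

test_that("codon-set simulation plants an exactly recoverable 2x2 table", {
  sim <- simulateCodonSet(80, 10,
    planted = list(fixedNonsyn = 5, fixedSyn = 10,
                   polyNonsyn = rep(0.5, 4), polySyn = rep(0.5, 8)),
    seed = 41)
  res <- mktTest(sim$alignment, cutoff = 0)
  expect_equal(unname(mktCounts(res)), c(5, 10, 4, 8))
  expect_equal(neutralityIndex(res), 1)
  expect_equal(mktAlpha(res), 0)

  empty <- simulateCodonSet(30, 6, planted = list(), seed = 42)
  expect_equal(unname(mktCounts(mktTest(empty$alignment, cutoff = 0))),
               c(0, 0, 0, 0))

  expect_error(simulateCodonSet(30, 10, planted = list(polySyn = 0.13),
                                seed = 1),
               "not representable")
  expect_error(simulateCodonSet(3, 10,
                                planted = list(fixedSyn = 5), seed = 1),
               "exceed")
})
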