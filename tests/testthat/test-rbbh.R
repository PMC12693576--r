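test_that("every gene is its own reciprocal best hit against an identical genome", {
  ref <- forgeReference(nGenes = 8, nContigs = 1, seed = 11)
  call <- reciprocalCall(geneIds(ref)[3], ref, ref)
  expect_identical(call$status, "PRESENT_RBBH")
  expect_equal(call$forward$identity, 1)
})

test_that("forged conserved genes are recovered and planted losses flagged", {
  fx <- smallCladeFixture()
  prelim <- calls(fx$res$prelim)
  truth <- fx$forged$truth
  conserved <- truth[truth$event == "conserved", ]
  expect_true(all(prelim[cbind(conserved$gene_id, conserved$species_id)] ==
                    "PRESENT_RBBH"))
  lost <- truth[truth$event == "lost", ]
  expect_true(all(prelim[cbind(lost$gene_id, lost$species_id)] ==
                    "ABSENT_PRELIM"))
  # matrix completeness: every cell filled, reference column all present
  expect_false(anyNA(prelim))
  expect_true(all(prelim[, "reference"] == "PRESENT_REFERENCE"))
})

test_that("a duplicated gene causing a rank-1 tie breaks reciprocity conservatively", {
  ref <- forgeReference(nGenes = 8, nContigs = 1, seed = 12)
  tgt <- withDuplicatedGene(ref, "g003")
  tgt@speciesId <- "dupsp"
  call <- reciprocalCall("g003", ref, tgt)
  expect_identical(call$status, "ABSENT_PRELIM")
  expect_identical(call$flag, "ambiguous_tie")
})

test_that("an empty target proteome yields all preliminary absences", {
  ref <- forgeReference(nGenes = 5, nContigs = 1, seed = 13)
  emptyGr <- GenomicRanges::GRanges()
  S4Vectors::mcols(emptyGr)$gene_id <- character()
  S4Vectors::mcols(emptyGr)$cds <- character()
  S4Vectors::mcols(emptyGr)$protein <- character()
  S4Vectors::mcols(emptyGr)$untranslatable <- logical()
  empty <- AnnotatedGenome("void",
                           Biostrings::DNAStringSet(c(c1 = "ACGTACGTACGT")),
                           emptyGr)
  rb <- suppressMessages(callMatrix(geneIds(ref), ref, list(void = empty)))
  expect_true(all(calls(rb$matrix)[, "void"] == "ABSENT_PRELIM"))
})

test_that("reciprocity is symmetric for clean orthologs", {
  fx <- smallCladeFixture()
  ref <- fx$ref; tgt <- fx$forged$genomes$near
  det <- fx$res$details
  present <- det[det$species_id == "near" & det$status == "PRESENT_RBBH", ]
  # calling from the target side pairs each subject back to the same gene
  for (i in sample(nrow(present), 5)) {
    fwdSubject <- present$forward_subject[i]
    back <- reciprocalCall(fwdSubject, tgt, ref)
    expect_identical(back$status, "PRESENT_RBBH")
    expect_identical(back$forward$subject_id, present$gene_id[i])
  }
})

test_that("increasing divergence never resurrects a planted loss", {
  ref <- forgeReference(nGenes = 10, nContigs = 1, seed = 14)
  for (d in c(10, 60)) {
    phylo <- PhylogenyConfig("reference", c(reference = 0, sp = d))
    forged <- suppressMessages(forgeClade(
      ref, phylo,
      events = data.frame(gene_id = "g005", species_id = "sp",
                          event = "lost"),
      seed = 14))
    rb <- suppressMessages(callMatrix(geneIds(ref), ref, forged$genomes))
    expect_identical(unname(calls(rb$matrix)["g005", "sp"]), "ABSENT_PRELIM")
  }
})
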