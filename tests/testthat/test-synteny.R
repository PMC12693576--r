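test_that("flanking anchors follow reference gene order", {
  ref <- forgeReference(nGenes = 10, nContigs = 1, seed = 21)
  a5 <- flankingAnchors("g005", ref)
  expect_identical(a5$upstream, c("g004", "g003", "g002"))
  expect_identical(a5$downstream, c("g006", "g007", "g008"))
  expect_false(a5$atContigEdge)

  a1 <- flankingAnchors("g001", ref)
  expect_identical(a1$upstream, character(0))
  expect_identical(a1$downstream, c("g002", "g003", "g004"))
  expect_true(a1$atContigEdge)

  k1 <- flankingAnchors("g005", ref, k = 1)
  expect_identical(k1$upstream, "g004")
  expect_identical(k1$downstream, "g006")
})

test_that("block location flags reflect the planted assembly events", {
  fx <- smallCladeFixture()
  ref <- fx$ref; res <- fx$res
  blocks <- res$resolution$blocks

  loss <- blocks[["g004|near"]]
  expect_true(loss$retained_synteny)
  expect_false(loss$anchors_split_across_contigs)
  expect_false(loss$end_of_contig)
  expect_identical(nrow(loss$located), 6L)     # all six anchors found

  split <- blocks[["g013|near"]]
  expect_false(split$retained_synteny)
  expect_true(split$anchors_split_across_contigs)

  contigEnd <- blocks[["g007|far"]]
  expect_false(contigEnd$retained_synteny)
  expect_true(contigEnd$end_of_contig)
})

test_that("rescue finds split genes and diverged loci but not clean losses", {
  fx <- smallCladeFixture()
  ref <- fx$ref
  thresholds <- orthologThresholds()
  blocks <- fx$res$resolution$blocks

  splitRescue <- rescueSearch("g013", blocks[["g013|near"]], ref,
                              fx$forged$genomes$near, thresholds)
  expect_true(splitRescue$rescued)
  expect_identical(splitRescue$mode, "split")
  expect_gte(splitRescue$combinedCoverage, thresholds$rescueCoverage)

  lossRescue <- rescueSearch("g004", blocks[["g004|near"]], ref,
                             fx$forged$genomes$near, thresholds)
  expect_false(lossRescue$rescued)

  divergedRescue <- rescueSearch("g016", blocks[["g016|far"]], ref,
                                 fx$forged$genomes$far, thresholds)
  expect_true(divergedRescue$rescued)   # nucleotide route despite <25% protein id
})

test_that("classification is total and matches the planted truth end-to-end", {
  fx <- smallCladeFixture()
  truth <- fx$forged$truth
  final <- calls(fx$res$final)
  got <- final[cbind(truth$gene_id, truth$species_id)]
  expect_identical(unname(got), truth$expected_call)
  # no preliminary status survives resolution
  expect_false(any(final == "ABSENT_PRELIM"))
  # zero false absences among planted conserved genes
  conserved <- truth[truth$event == "conserved", ]
  expect_false(any(isAbsentCall(
    final[cbind(conserved$gene_id, conserved$species_id)])))
})

test_that("in-silico validation confirms losses and catches planted presence", {
  fx <- smallCladeFixture()
  ref <- fx$ref
  vals <- fx$res$resolution$validations
  expect_true(all(vals$status[vals$gene_id == "g004"] == "VALIDATED_ABSENT"))

  # adversarial: validate the interval of the diverged-but-present locus
  blocks <- fx$res$resolution$blocks
  v <- inSilicoValidation("g016", blocks[["g016|far"]], ref,
                          fx$forged$genomes$far)
  expect_identical(v$status, "CONTRADICTED")

  # an interval far beyond the amplicon bound is skipped, not validated
  tiny <- orthologThresholds(maxAmplicon = 10)
  v2 <- inSilicoValidation("g004", blocks[["g004|near"]], ref,
                           fx$forged$genomes$near, tiny)
  expect_identical(v2$status, "NOT_VALIDATED")
})

test_that("retained synteny degrades monotonically as anchors are removed", {
  fx <- smallCladeFixture()
  ref <- fx$ref; tgt <- fx$forged$genomes$near
  anchors <- flankingAnchors("g004", ref)
  seen <- logical(0)
  for (keep in 3:0) {
    a <- anchors
    a$upstream <- head(a$upstream, keep)
    b <- suppressMessages(locateBlock(a, tgt, ref))
    seen <- c(seen, b$retained_synteny)
  }
  expect_identical(seen, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(diff(seen) > 0))   # never TRUE after FALSE
})
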