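toyMatrix <- function() {
  m <- matrix("PRESENT_RBBH", 10, 3,
              dimnames = list(sprintf("g%02d", 1:10), c("spA", "spB", "spC")))
  m[c("g01", "g02"), "spB"] <- "ABSENT_SYNTENY"
  m["g03", "spC"] <- "UNRESOLVED_CONTIG_END"
  PresenceMatrix(m, caller = "rbbh_synteny")
}

test_that("per-species summaries count absences over the focal total", {
  s <- perSpeciesSummary(toyMatrix())
  expect_equal(s$n_absent[s$species == "spB"], 2)
  expect_equal(s$pct_absent[s$species == "spB"], 20)
  expect_equal(s$n_absent[s$species == "spA"], 0)
  # unresolved cells are conservatively not absences, unless switched
  expect_equal(s$n_absent[s$species == "spC"], 0)
  s2 <- perSpeciesSummary(toyMatrix(), countUnresolved = TRUE)
  expect_equal(s2$n_absent[s2$species == "spC"], 1)
  # percentage consistency with the counts
  expect_equal(s$pct_absent, round(100 * s$n_absent / 10, 2))
})

test_that("any-absence genes equal the union of per-species absent sets", {
  pm <- toyMatrix()
  expect_identical(sort(anyAbsenceGenes(pm)), c("g01", "g02"))
  m <- calls(pm)
  unionSet <- sort(unique(unlist(lapply(colnames(m), function(s)
    rownames(m)[isAbsentCall(m[, s])]))))
  expect_identical(sort(anyAbsenceGenes(pm)), unionSet)
  allPresent <- PresenceMatrix(
    matrix("PRESENT_RBBH", 3, 2,
           dimnames = list(paste0("g", 1:3), c("a", "b"))), "rbbh")
  expect_identical(anyAbsenceGenes(allPresent), character(0))
})

test_that("category and defect summaries reproduce the expected percentages", {
  nGenes <- 21
  ids <- sprintf("g%02d", seq_len(nGenes))
  m <- matrix("PRESENT_RBBH", nGenes, 2, dimnames = list(ids, c("s1", "s2")))
  m[c("g01", "g02"), "s1"] <- "ABSENT_SYNTENY"   # both in the small category
  pm <- PresenceMatrix(m, "rbbh_synteny")
  ann <- data.frame(
    gene_id = ids,
    functional_category = c(rep("kinetochore", 6), rep("proteasome", 15)),
    defect_type = c(rep("gsc_loss", 14), rep("oocyte", 7)),
    stringsAsFactors = FALSE)
  cs <- categorySummary(pm, ann)
  kin <- cs$categories[cs$categories$group == "kinetochore", ]
  expect_equal(kin$n_genes, 6); expect_equal(kin$n_with_absence, 2)
  expect_equal(kin$pct, 33.33)
  pro <- cs$categories[cs$categories$group == "proteasome", ]
  expect_equal(pro$pct, 0)
  gl <- cs$defects[cs$defects$group == "gsc_loss", ]
  expect_equal(gl$pct, round(100 * 2 / 14, 2))

  # a gene in several categories counts once in each
  ann2 <- ann
  ann2$functional_category[1] <- "kinetochore;proteasome"
  cs2 <- categorySummary(pm, ann2)
  expect_equal(cs2$categories$n_with_absence[
    cs2$categories$group == "proteasome"], 1)
  expect_error(categorySummary(pm, ann[-1, ]), "unannotated")
})

test_that("network co-absence counts same-species pairs and unevaluated nodes", {
  ids <- c("g1", "g2", "i1", "i2")
  m <- matrix("PRESENT_RBBH", 4, 2, dimnames = list(ids, c("s1", "s2")))
  m["g1", "s1"] <- "ABSENT_SYNTENY"
  m["i1", "s1"] <- "ABSENT_SYNTENY"     # co-absent with g1 in s1
  m["i2", "s2"] <- "ABSENT_NO_SYNTENY"  # absent, but in another species
  pm <- PresenceMatrix(m, "rbbh_synteny")
  net <- data.frame(gene_id = c("g1", "g1", "g1"),
                    interactor_id = c("i1", "i2", "unseen"),
                    stringsAsFactors = FALSE)
  nc <- networkCooccurrence(pm, net)
  row <- nc$perGene[nc$perGene$gene_id == "g1", ]
  expect_equal(row$network_size, 3)
  expect_equal(row$n_unevaluated, 1)
  expect_equal(row$n_interactors_absent, 2)
  expect_equal(row$n_coabsent_same_species, 1)
  expect_equal(unname(nc$global["n_with_network_absence"]), 1)

  # an absent focal gene with an empty network reports zeros
  nc2 <- networkCooccurrence(pm, net[net$gene_id == "none", , drop = FALSE])
  row2 <- nc2$perGene[nc2$perGene$gene_id == "g1", ]
  expect_equal(unname(unlist(
    row2[, c("network_size", "n_interactors_absent",
             "n_coabsent_same_species")])), c(0, 0, 0))
})

test_that("external predictions import with the inclusive 25% identity rule", {
  tab <- data.frame(gene_id = c("g1", "g1", "g2", NA),
                    species_id = c("spA", "spB", "spA", "spB"),
                    identity = c(24.9, 25.0, 80, 50))
  expect_warning(pm <- importExternalPredictions(
    tab, geneSet = c("g1", "g2"), speciesIds = c("spA", "spB")),
    "malformed")
  m <- calls(pm)
  expect_identical(unname(m["g1", "spA"]), "ABSENT")    # 24.9% fails
  expect_identical(unname(m["g1", "spB"]), "PRESENT")   # boundary inclusive
  expect_identical(unname(m["g2", "spB"]), "ABSENT")    # missing pair
  expect_identical(caller(pm), "ensembl_import")

  expect_warning(pmEmpty <- importExternalPredictions(
    data.frame(gene_id = character(), species_id = character(),
               identity = numeric()),
    geneSet = "g1", speciesIds = "spA"), "all absent")
  expect_true(all(calls(pmEmpty) == "ABSENT"))
})
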