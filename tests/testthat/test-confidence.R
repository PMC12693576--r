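mkMatrix <- function(cells, genesIds, speciesIds) {
  m <- matrix(cells, length(genesIds), length(speciesIds), byrow = TRUE,
              dimnames = list(genesIds, speciesIds))
  PresenceMatrix(m, caller = "rbbh_synteny")
}

phylo5 <- PhylogenyConfig("ref",
  c(ref = 0, near = 5, mid = 30, deep = 70, deepest = 250))

test_that("a deeper present witness gives HIGH confidence to an absence", {
  pm <- mkMatrix(c("PRESENT_REFERENCE", "PRESENT_RBBH", "ABSENT_SYNTENY",
                   "PRESENT_RBBH", "PRESENT_RESCUED"),
                 "g1", c("ref", "near", "mid", "deep", "deepest"))
  t <- tierAbsences(pm, phylo5)
  expect_identical(t$tier, "HIGH")
  expect_true(t$gene_support)
})

test_that("absences confined to the deepest lineages are LOW confidence", {
  pm <- mkMatrix(c("PRESENT_REFERENCE", "PRESENT_RBBH", "PRESENT_RBBH",
                   "ABSENT_SYNTENY", "ABSENT_NO_SYNTENY"),
                 "g1", c("ref", "near", "mid", "deep", "deepest"))
  t <- tierAbsences(pm, phylo5)
  expect_identical(t$tier[t$species_id == "deepest"], "LOW")
  # the shallower of the two absences still has no witness at >= divergence
  expect_identical(t$tier[t$species_id == "deep"], "LOW")
})

test_that("equally divergent present witnesses count (ties allowed)", {
  phyloTie <- PhylogenyConfig("ref", c(ref = 0, s1 = 70, s2 = 70))
  pm <- mkMatrix(c("PRESENT_REFERENCE", "ABSENT_SYNTENY", "PRESENT_RBBH"),
                 "g1", c("ref", "s1", "s2"))
  expect_identical(tierAbsences(pm, phyloTie)$tier, "HIGH")
})

test_that("in-silico validation takes precedence over lineage support", {
  pm <- mkMatrix(c("PRESENT_REFERENCE", "PRESENT_RBBH", "ABSENT_SYNTENY",
                   "PRESENT_RBBH", "PRESENT_RBBH"),
                 "g1", c("ref", "near", "mid", "deep", "deepest"))
  vals <- data.frame(gene_id = "g1", species_id = "mid",
                     status = "VALIDATED_ABSENT")
  t <- tierAbsences(pm, phylo5, vals)
  expect_identical(t$tier, "VALIDATED")
  expect_match(t$rationale, "witness")   # lineage support noted
})

test_that("tiering ignores species column order and never drops with deeper witnesses", {
  cells <- c("PRESENT_REFERENCE", "PRESENT_RBBH", "ABSENT_SYNTENY",
             "PRESENT_RBBH", "ABSENT_NO_SYNTENY")
  sp <- c("ref", "near", "mid", "deep", "deepest")
  pm <- mkMatrix(cells, "g1", sp)
  perm <- c(5, 3, 1, 4, 2)
  pm2 <- PresenceMatrix(calls(pm)[, perm, drop = FALSE], "rbbh_synteny")
  t1 <- tierAbsences(pm, phylo5)
  t2 <- tierAbsences(pm2, phylo5)
  o1 <- t1[order(t1$species_id), c("species_id", "tier")]
  o2 <- t2[order(t2$species_id), c("species_id", "tier")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)

  # adding a PRESENT witness at deeper divergence never lowers a tier
  rank <- c(LOW = 1, HIGH = 2, VALIDATED = 3)
  cells3 <- cells; cells3[5] <- "PRESENT_RBBH"
  t3 <- tierAbsences(mkMatrix(cells3, "g1", sp), phylo5)
  for (s in intersect(t1$species_id, t3$species_id))
    expect_gte(rank[t3$tier[t3$species_id == s]],
               rank[t1$tier[t1$species_id == s]])
})

test_that("a species missing from the phylogeny is an error", {
  pm <- mkMatrix(c("PRESENT_REFERENCE", "ABSENT_SYNTENY"), "g1",
                 c("ref", "unknown_sp"))
  expect_error(tierAbsences(pm, phylo5), "missing from phylogeny")
})
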