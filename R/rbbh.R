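## Stage 1: reciprocal-best-hit ortholog calling ------------------------

#' Threshold set for the ortholog pipeline
#'
#' Collects the tunable cutoffs used across the search, RBBH and synteny
#' stages.  A forward protein hit is "real" when its score and query
#' coverage pass `minScoreProtein` / `minCoverage` (and `minIdentity`, if
#' set; off by default).  Nucleotide rescue hits must pass `minScoreNt`,
#' and a rescue succeeds when the union of rescued query spans covers at
#' least `rescueCoverage` of the CDS.  `maxAmplicon` bounds the
#' inter-anchor interval submitted to in-silico validation, and
#' `endMargin` is how close (bp) an innermost located anchor must be to a
#' contig edge for the missing-gene position to be flagged as running off
#' the contig.
#'
#' @param minScoreProtein minimum raw protein alignment score.
#' @param minCoverage minimum query coverage of a forward protein hit.
#' @param minIdentity optional minimum identity fraction (default `NULL`,
#'   i.e. no identity filter).
#' @param minScoreNt minimum raw nucleotide alignment score.
#' @param rescueCoverage combined query-coverage needed to rescue.
#' @param maxAmplicon largest inter-anchor interval (bp) validated.
#' @param endMargin bp from a contig edge that counts as "at the end".
#' @param validationMinCoverage query coverage above which a hit inside a
#'   validated interval contradicts the absence.
#' @return a named list of thresholds.
#' @export
orthologThresholds <- function(minScoreProtein = 60, minCoverage = 0.5,
                               minIdentity = NULL, minScoreNt = 50,
                               rescueCoverage = 0.8, maxAmplicon = 50000,
                               endMargin = 20000,
                               validationMinCoverage = 0.2) {
  list(minScoreProtein = minScoreProtein, minCoverage = minCoverage,
       minIdentity = minIdentity, minScoreNt = minScoreNt,
       rescueCoverage = rescueCoverage, maxAmplicon = maxAmplicon,
       endMargin = endMargin, validationMinCoverage = validationMinCoverage)
}

# full forward/reverse hit tables between two proteomes; built once per
# species pair and reused by the RBBH and synteny stages
.searchIndex <- function(reference, target, scoring = proteinScoring()) {
  refProt <- proteome(reference)
  tgtProt <- proteome(target)
  if (length(tgtProt) == 0L || length(refProt) == 0L)
    return(list(fwd = setNames(vector("list", length(refProt)),
                               names(refProt)),
                rev = list()))
  ap <- .alignPairs(refProt, tgtProt, scoring)
  cols <- c("subject_id", "score", "identity", "query_coverage",
            "subject_coverage", "qstart", "qend", "sstart", "send")
  fwd <- lapply(split(ap, ap$query_id), function(d) .sortHits(d[, cols]))
  # reverse direction: same alignments with the roles swapped
  rv <- data.frame(query_id = ap$subject_id, subject_id = ap$query_id,
                   score = ap$score, identity = ap$identity,
                   query_coverage = ap$subject_coverage,
                   subject_coverage = ap$query_coverage,
                   qstart = ap$sstart, qend = ap$send,
                   sstart = ap$qstart, send = ap$qend,
                   stringsAsFactors = FALSE)
  rev <- lapply(split(rv, rv$query_id), function(d) .sortHits(d[, cols]))
  list(fwd = fwd[names(refProt)], rev = rev[names(tgtProt)])
}

.bestHit <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(NULL)
  tie <- nrow(tab) >= 2L && tab$score[2] == tab$score[1] &&
    tab$identity[2] == tab$identity[1]
  list(hit = tab[1, , drop = FALSE], tie = tie)
}

.passesForward <- function(hit, thresholds) {
  ok <- hit$score >= thresholds$minScoreProtein &&
    hit$query_coverage >= thresholds$minCoverage
  if (ok && !is.null(thresholds$minIdentity))
    ok <- hit$identity >= thresholds$minIdentity
  ok
}

# core decision for one (gene, species); index carries fwd/rev hit tables
.rbbhDecide <- function(geneId, reference, index, thresholds) {
  mc <- mcols(genes(reference))
  untr <- mc$untranslatable[match(geneId, mc$gene_id)]
  if (isTRUE(untr))
    return(list(status = "ABSENT_PRELIM", flag = "no_protein",
                forward = NULL, reverse = NULL))
  fb <- .bestHit(index$fwd[[geneId]])
  if (is.null(fb) || !.passesForward(fb$hit, thresholds))
    return(list(status = "ABSENT_PRELIM", flag = "no_forward_hit",
                forward = if (is.null(fb)) NULL else fb$hit, reverse = NULL))
  if (fb$tie)
    return(list(status = "ABSENT_PRELIM", flag = "ambiguous_tie",
                forward = fb$hit, reverse = NULL))
  subjectId <- fb$hit$subject_id
  rb <- .bestHit(index$rev[[subjectId]])
  if (is.null(rb))
    return(list(status = "ABSENT_PRELIM", flag = "no_reverse_hit",
                forward = fb$hit, reverse = NULL))
  if (rb$tie)
    return(list(status = "ABSENT_PRELIM", flag = "ambiguous_tie",
                forward = fb$hit, reverse = rb$hit))
  if (rb$hit$subject_id == geneId)
    list(status = "PRESENT_RBBH", flag = "", forward = fb$hit,
         reverse = rb$hit)
  else
    list(status = "ABSENT_PRELIM", flag = "reciprocity_broken",
         forward = fb$hit, reverse = rb$hit)
}

#' Reciprocal-best-hit call for one gene against one target genome
#'
#' Runs the forward protein search of the gene's representative protein
#' against the target proteome; if the rank-1 hit passes the thresholds, the
#' reverse search of that subject against the reference proteome must rank
#' the original gene first for a `PRESENT_RBBH` call.  Rank-1 ties in either
#' direction yield `ABSENT_PRELIM` with flag `ambiguous_tie`
#' (conservatively pushed to the synteny stage); untranslatable genes yield
#' `ABSENT_PRELIM` with flag `no_protein`.
#'
#' @param geneId a gene id of the reference genome.
#' @param reference,target [AnnotatedGenome-class] objects.
#' @param thresholds see [orthologThresholds()].
#' @param scoring protein scoring scheme.
#' @return a list: `gene_id`, `species_id`, `status`
#'   (`PRESENT_RBBH`/`ABSENT_PRELIM`), `flag`, `forward` and `reverse`
#'   rank-1 hit rows (or `NULL`).
#' @examples
#' ref <- forgeReference(nGenes = 8, seed = 2)
#' reciprocalCall(geneIds(ref)[1], ref, ref)$status  # self vs self
#' @export
reciprocalCall <- function(geneId, reference, target,
                           thresholds = orthologThresholds(),
                           scoring = proteinScoring()) {
  stopifnot(geneId %in% geneIds(reference))
  index <- .searchIndex(reference, target, scoring)
  out <- .rbbhDecide(geneId, reference, index, thresholds)
  c(list(gene_id = geneId, species_id = speciesId(target)), out)
}

#' Preliminary presence matrix by RBBH over a gene list
#'
#' One reciprocal-best-hit call per (gene, species).  The reference species
#' contributes a first column of `PRESENT_REFERENCE`.  The returned object
#' also carries the per-species search indexes, which the synteny stage
#' reuses to locate anchors.
#'
#' @param geneSet character vector of focal reference gene ids.
#' @param reference reference [AnnotatedGenome-class].
#' @param targets named list of target [AnnotatedGenome-class] objects.
#' @param thresholds see [orthologThresholds()].
#' @param scoring protein scoring scheme.
#' @return a list with elements `matrix` (a [PresenceMatrix-class], caller
#'   `"rbbh"`), `details` (data.frame of per-call evidence) and `index`
#'   (per-species search indexes, reused by [resolveAbsences()]).
#' @export
callMatrix <- function(geneSet, reference, targets,
                       thresholds = orthologThresholds(),
                       scoring = proteinScoring()) {
  stopifnot(all(geneSet %in% geneIds(reference)))
  if (is.null(names(targets)))
    names(targets) <- vapply(targets, speciesId, character(1))
  speciesIds <- names(targets)
  m <- matrix("PRESENT_REFERENCE", length(geneSet),
              1L + length(speciesIds),
              dimnames = list(geneSet, c(speciesId(reference), speciesIds)))
  details <- list()
  indexes <- list()
  for (sp in speciesIds) {
    idx <- .searchIndex(reference, targets[[sp]], scoring)
    indexes[[sp]] <- idx
    for (g in geneSet) {
      dec <- .rbbhDecide(g, reference, idx, thresholds)
      m[g, sp] <- dec$status
      fwd <- dec$forward
      details[[length(details) + 1L]] <- data.frame(
        gene_id = g, species_id = sp, status = dec$status, flag = dec$flag,
        forward_subject = if (!is.null(fwd)) fwd$subject_id else NA_character_,
        forward_score = if (!is.null(fwd)) fwd$score else NA_real_,
        forward_identity = if (!is.null(fwd)) fwd$identity else NA_real_,
        forward_coverage = if (!is.null(fwd)) fwd$query_coverage else NA_real_,
        reverse_subject = if (!is.null(dec$reverse)) dec$reverse$subject_id
                          else NA_character_,
        stringsAsFactors = FALSE)
    }
    .stageMsg("rbbh %s: %d/%d present", sp,
              sum(m[, sp] == "PRESENT_RBBH"), length(geneSet))
  }
  list(matrix = PresenceMatrix(m, caller = "rbbh"),
       details = do.call(rbind, details), index = indexes)
}

#' Naive forward-threshold presence calls
#'
#' A deliberately simple single-direction caller (comparable to importing a
#' precomputed ortholog table and thresholding it): a gene is `PRESENT` in a
#' species iff its best forward protein hit reaches `minIdentity` and
#' `minCoverage`.  No reciprocity, no synteny.  Used as the most
#' absence-prone strategy in the three-caller comparison.
#'
#' @inheritParams callMatrix
#' @param minIdentity,minCoverage thresholds on the best forward hit.
#' @return a [PresenceMatrix-class] with caller `"naive"`.
#' @export
naiveCalls <- function(geneSet, reference, targets, minIdentity = 0.5,
                       minCoverage = 0.9, scoring = proteinScoring()) {
  if (is.null(names(targets)))
    names(targets) <- vapply(targets, speciesId, character(1))
  refProt <- proteome(reference)
  m <- matrix("PRESENT_REFERENCE", length(geneSet),
              1L + length(targets),
              dimnames = list(geneSet, c(speciesId(reference), names(targets))))
  for (sp in names(targets)) {
    tgtProt <- proteome(targets[[sp]])
    m[, sp] <- "ABSENT"
    if (length(tgtProt)) {
      qset <- refProt[intersect(geneSet, names(refProt))]
      ap <- .alignPairs(qset, tgtProt, scoring)
      for (d in split(ap, ap$query_id)) {
        best <- .sortHits(d)[1, ]
        if (best$identity >= minIdentity &&
              best$query_coverage >= minCoverage)
          m[d$query_id[1], sp] <- "PRESENT"
      }
    }
  }
  PresenceMatrix(m, caller = "naive")
}
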