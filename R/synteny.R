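## Stage 2: synteny-aware re-evaluation of preliminary absences ---------

#' Flanking anchor genes for a focal gene
#'
#' Up to `k` genes on each side of the focal gene, by reference gene order
#' on the gene's contig, nearest first.  A side near a contig end yields
#' fewer anchors and sets `atContigEdge`; a gene alone on its contig yields
#' an empty anchor set.
#'
#' @param geneId focal reference gene id.
#' @param reference the reference [AnnotatedGenome-class].
#' @param k anchors per side (default 3, the standard flanking window).
#' @return a list: `gene_id`, `upstream`, `downstream` (character vectors,
#'   nearest first), `atContigEdge` (logical).
#' @examples
#' ref <- forgeReference(nGenes = 10, nContigs = 1, seed = 3)
#' flankingAnchors(geneIds(ref)[5], ref)$upstream
#' @export
flankingAnchors <- function(geneId, reference, k = 3) {
  gr <- genes(reference)
  ids <- mcols(gr)$gene_id
  i <- match(geneId, ids)
  if (is.na(i)) stop("gene ", geneId, " not in reference")
  ctg <- as.character(seqnames(gr))[i]
  onCtg <- which(as.character(seqnames(gr)) == ctg)   # already in start order
  pos <- match(i, onCtg)
  up <- rev(onCtg[max(1, pos - k):(pos - 1)])         # nearest first
  if (pos == 1L) up <- integer()
  dn <- onCtg[(pos + 1):min(length(onCtg), pos + k)]
  if (pos == length(onCtg)) dn <- integer()
  list(gene_id = geneId, upstream = ids[up], downstream = ids[dn],
       atContigEdge = length(up) < k || length(dn) < k)
}

# a reference anchor is "located" in the target when it has a reciprocal
# best hit there (guards against anchoring on paralogs)
.locateAnchor <- function(anchorId, index, thresholds, target) {
  dec <- .rbbhDecide(anchorId, attr(index, "reference"), index, thresholds)
  if (dec$status != "PRESENT_RBBH") return(NULL)
  tgt <- dec$forward$subject_id
  gr <- genes(target)
  j <- match(tgt, mcols(gr)$gene_id)
  list(anchor_id = anchorId, target_gene = tgt,
       contig = as.character(seqnames(gr))[j],
       start = start(gr)[j], end = end(gr)[j],
       strand = as.character(strand(gr))[j])
}

#' Locate the syntenic block for an anchor set in a target genome
#'
#' Each anchor is sought by reciprocal protein search in the target; the
#' block is the interval between the innermost located upstream and
#' downstream anchors when they share a contig.  Flags:
#' `retained_synteny` -- at least one anchor located on each side, innermost
#' pair co-located on one contig (anchor order/orientation is not required,
#' only co-location); `anchors_split_across_contigs` -- both sides located
#' but the innermost pair lies on different contigs (interval undefined);
#' `end_of_contig` -- the located evidence stops at a contig edge within
#' `endMargin` bp in the direction where the focal gene should be.
#'
#' @param anchors an anchor set from [flankingAnchors()].
#' @param target target [AnnotatedGenome-class].
#' @param reference reference [AnnotatedGenome-class].
#' @param thresholds see [orthologThresholds()].
#' @param index optional precomputed search index (from [callMatrix()]).
#' @param scoring protein scoring scheme.
#' @return a list: `species_id`, `located` (data.frame of located anchors
#'   with side/contig/coordinates), `contig` (shared contig or `NA`),
#'   `interval` (c(start, end) between innermost anchors, or `NULL`),
#'   flags `retained_synteny`, `end_of_contig`,
#'   `anchors_split_across_contigs`.
#' @export
locateBlock <- function(anchors, target, reference,
                        thresholds = orthologThresholds(), index = NULL,
                        scoring = proteinScoring()) {
  if (length(anchors$upstream) == 0L && length(anchors$downstream) == 0L)
    return(list(species_id = speciesId(target), located = NULL, contig = NA,
                interval = NULL, retained_synteny = FALSE,
                end_of_contig = FALSE, anchors_split_across_contigs = FALSE))
  if (is.null(index)) index <- .searchIndex(reference, target, scoring)
  attr(index, "reference") <- reference
  locSide <- function(idsVec, side) {
    out <- list()
    for (a in idsVec) {
      la <- .locateAnchor(a, index, thresholds, target)
      if (!is.null(la)) out[[length(out) + 1L]] <- c(la, list(side = side))
    }
    out
  }
  upLoc <- locSide(anchors$upstream, "upstream")
  dnLoc <- locSide(anchors$downstream, "downstream")
  located <- c(upLoc, dnLoc)
  locdf <- if (length(located))
    do.call(rbind, lapply(located, function(x)
      data.frame(anchor_id = x$anchor_id, target_gene = x$target_gene,
                 contig = x$contig, start = x$start, end = x$end,
                 strand = x$strand, side = x$side,
                 stringsAsFactors = FALSE)))
  else NULL

  innUp <- if (length(upLoc)) upLoc[[1]] else NULL   # nearest-first order
  innDn <- if (length(dnLoc)) dnLoc[[1]] else NULL
  retained <- FALSE; splitFlag <- FALSE; interval <- NULL; ctg <- NA_character_
  if (!is.null(innUp) && !is.null(innDn)) {
    if (innUp$contig == innDn$contig) {
      retained <- TRUE
      ctg <- innUp$contig
      left <- min(innUp$end, innDn$end)
      right <- max(innUp$start, innDn$start)
      interval <- c(left + 1L, right - 1L)
      if (interval[2] < interval[1]) interval <- c(interval[1], interval[1] - 1L)
    } else splitFlag <- TRUE
  }
  # contig-edge flag: evidence stops near an edge of a located anchor's contig
  endFlag <- FALSE
  if (!retained && !is.null(locdf)) {
    ctgW <- setNames(width(contigs(target)), names(contigs(target)))
    inner <- Filter(Negate(is.null), list(innUp, innDn))
    for (x in inner) {
      distLeft <- x$start - 1L
      distRight <- ctgW[[x$contig]] - x$end
      if (min(distLeft, distRight) <= thresholds$endMargin) endFlag <- TRUE
    }
  }
  list(species_id = speciesId(target), located = locdf, contig = ctg,
       interval = interval, retained_synteny = retained,
       end_of_contig = endFlag, anchors_split_across_contigs = splitFlag)
}

# collect target regions to re-search: the inter-anchor interval plus every
# contig carrying a located anchor (captures split genes)
.rescueRegions <- function(block, target) {
  regions <- list()
  if (isTRUE(block$retained_synteny) && !is.null(block$interval) &&
      block$interval[2] >= block$interval[1]) {
    regions[["interval"]] <- list(
      contig = block$contig, start = block$interval[1], end = block$interval[2])
  }
  if (!is.null(block$located)) {
    for (ctg in unique(block$located$contig))
      regions[[paste0("contig:", ctg)]] <- list(
        contig = ctg, start = 1L, end = width(contigs(target))[[
          match(ctg, names(contigs(target)))]])
  }
  regions
}

#' Nucleotide/protein rescue search for a preliminarily absent gene
#'
#' Searches the gene's CDS (nucleotide) and protein against (a) the
#' inter-anchor interval and (b) every contig carrying a located anchor.
#' A single hit covering at least `rescueCoverage` of the CDS rescues the
#' gene; partial hits on two or more contigs whose merged query coverage
#' reaches `rescueCoverage` count as a split-gene rescue.  The protein
#' route compares the gene product against annotated target proteins whose
#' gene models overlap the searched regions (catching nucleotide-diverged
#' but annotated orthologs); highly protein-diverged genes are typically
#' caught by the nucleotide route.
#'
#' @param geneId focal reference gene id.
#' @param block a block from [locateBlock()].
#' @param reference,target [AnnotatedGenome-class] objects.
#' @param thresholds see [orthologThresholds()].
#' @return a list: `rescued` (logical), `mode`
#'   (`"single"`/`"split"`/`"none"`), `combinedCoverage`, `hits`
#'   (data.frame of passing nucleotide hits per region).
#' @export
rescueSearch <- function(geneId, block, reference, target,
                         thresholds = orthologThresholds()) {
  regions <- .rescueRegions(block, target)
  cds <- cdsSeqs(reference)[[geneId]]
  ntScoring <- nucleotideScoring()
  hits <- list()
  for (nm in names(regions)) {
    rg <- regions[[nm]]
    seqRegion <- subseq(contigs(target)[[rg$contig]], rg$start, rg$end)
    if (length(seqRegion) < 10L) next
    db <- DNAStringSet(setNames(list(seqRegion), rg$contig))
    fw <- searchHits(cds, db, ntScoring, minScore = thresholds$minScoreNt)
    rv <- searchHits(reverseComplement(cds), db, ntScoring,
                     minScore = thresholds$minScoreNt)
    if (nrow(rv)) {   # express reverse-strand hits in query coordinates
      qlen <- length(cds)
      tmp <- rv$qstart
      rv$qstart <- qlen - rv$qend + 1L
      rv$qend <- qlen - tmp + 1L
    }
    both <- rbind(fw, rv)
    if (nrow(both)) {
      both$region <- nm
      both$contig <- rg$contig
      hits[[length(hits) + 1L]] <- both[which.max(both$score), , drop = FALSE]
    }
  }
  hitdf <- if (length(hits)) do.call(rbind, hits) else NULL

  # protein route: annotated target genes inside the searched regions
  protRescued <- FALSE
  if (length(regions)) {
    regionContigs <- unique(vapply(regions, `[[`, character(1), "contig"))
    gr <- genes(target)
    onRegion <- mcols(gr)$gene_id[
      as.character(seqnames(gr)) %in% regionContigs &
        !mcols(gr)$untranslatable]
    refProt <- proteome(reference)
    if (length(onRegion) && geneId %in% names(refProt)) {
      ph <- searchHits(refProt[[geneId]],
                       proteome(target)[onRegion], proteinScoring(),
                       minScore = thresholds$minScoreProtein)
      protRescued <- nrow(ph) > 0 &&
        ph$query_coverage[1] >= thresholds$rescueCoverage
    }
  }

  combined <- 0; mode <- "none"
  if (!is.null(hitdf)) {
    qlen <- length(cds)
    covRanges <- IRanges(pmax(1L, hitdf$qstart), pmin(qlen, hitdf$qend))
    combined <- sum(width(reduce(covRanges))) / qlen
    if (any(hitdf$query_coverage >= thresholds$rescueCoverage)) {
      mode <- "single"
    } else if (length(unique(hitdf$contig)) >= 2L &&
               combined >= thresholds$rescueCoverage) {
      mode <- "split"
    }
  }
  if (mode == "none" && protRescued) mode <- "single"
  list(rescued = mode != "none", mode = mode,
       combinedCoverage = combined, hits = hitdf)
}

#' Resolve one preliminary absence to a final status
#'
#' Total classification of an `ABSENT_PRELIM` call: rescued evidence gives
#' `PRESENT_RESCUED`; otherwise retained synteny gives `ABSENT_SYNTENY`;
#' otherwise a contig-edge signal without both sides co-located gives
#' `UNRESOLVED_CONTIG_END`; everything else is `ABSENT_NO_SYNTENY`.
#'
#' @param prelim a call from [reciprocalCall()] (status `ABSENT_PRELIM`).
#' @param block a block from [locateBlock()].
#' @param rescue a result from [rescueSearch()].
#' @return a list: `gene_id`, `species_id`, `status`, `evidence` string.
#' @export
classifyAbsence <- function(prelim, block, rescue) {
  stopifnot(prelim$status == "ABSENT_PRELIM")
  status <-
    if (isTRUE(rescue$rescued)) "PRESENT_RESCUED"
    else if (isTRUE(block$retained_synteny)) "ABSENT_SYNTENY"
    else if (isTRUE(block$end_of_contig)) "UNRESOLVED_CONTIG_END"
    else "ABSENT_NO_SYNTENY"
  ev <- sprintf(
    "prelim=%s; retained_synteny=%s; end_of_contig=%s; split_anchors=%s; rescue=%s(cov=%.2f)",
    prelim$flag, block$retained_synteny, block$end_of_contig,
    block$anchors_split_across_contigs, rescue$mode, rescue$combinedCoverage)
  list(gene_id = prelim$gene_id, species_id = block$species_id,
       status = status, evidence = ev)
}

.sixFrames <- function(dna) {
  frames <- list()
  rc <- reverseComplement(dna)
  for (f in 1:3) {
    for (s in list(fwd = dna, rev = rc)) {
      if (length(s) < f + 2L) next
      sub <- subseq(s, f, f + ((length(s) - f + 1L) %/% 3L) * 3L - 1L)
      if (length(sub) >= 3L)
        frames[[length(frames) + 1L]] <-
          chartr("*", "X", as.character(suppressWarnings(
            translate(sub, if.fuzzy.codon = "solve"))))
    }
  }
  unlist(frames)
}

#' In-silico validation of an absence across a retained syntenic block
#'
#' Electronic analogue of amplifying and sequencing the region between
#' retained syntenic genes: extracts the inter-anchor interval (the
#' "amplicon"), then scans it with a nucleotide search for the focal CDS
#' and a six-frame translation search for the focal protein.  No hit above
#' thresholds gives `VALIDATED_ABSENT`; a hit flags `CONTRADICTED`.
#' Intervals longer than `maxAmplicon` are skipped as `NOT_VALIDATED`
#' (prohibitively large gaps).
#'
#' @param geneId focal reference gene id.
#' @param block a block from [locateBlock()] with retained synteny.
#' @param reference,target [AnnotatedGenome-class] objects.
#' @param thresholds see [orthologThresholds()].
#' @return a list: `gene_id`, `species_id`, `status` (`VALIDATED_ABSENT` /
#'   `CONTRADICTED` / `NOT_VALIDATED`), `ampliconWidth`, `amplicon`
#'   (character, "" when not validated).
#' @export
inSilicoValidation <- function(geneId, block, reference, target,
                               thresholds = orthologThresholds()) {
  if (!isTRUE(block$retained_synteny) || is.null(block$interval))
    return(list(gene_id = geneId, species_id = block$species_id,
                status = "NOT_VALIDATED", ampliconWidth = NA_integer_,
                amplicon = ""))
  wd <- block$interval[2] - block$interval[1] + 1L
  if (wd > thresholds$maxAmplicon)
    return(list(gene_id = geneId, species_id = block$species_id,
                status = "NOT_VALIDATED", ampliconWidth = wd, amplicon = ""))
  if (wd < 1L)
    return(list(gene_id = geneId, species_id = block$species_id,
                status = "VALIDATED_ABSENT", ampliconWidth = 0L,
                amplicon = ""))
  amplicon <- subseq(contigs(target)[[block$contig]],
                     block$interval[1], block$interval[2])
  cds <- cdsSeqs(reference)[[geneId]]
  db <- DNAStringSet(setNames(list(amplicon), "amplicon"))
  found <- FALSE
  for (q in list(cds, reverseComplement(cds))) {
    h <- searchHits(q, db, nucleotideScoring(),
                    minScore = thresholds$minScoreNt)
    if (nrow(h) && any(h$query_coverage >= thresholds$validationMinCoverage))
      found <- TRUE
  }
  if (!found) {
    mc <- mcols(genes(reference))
    prot <- mc$protein[match(geneId, mc$gene_id)]
    if (!is.na(prot)) {
      frames <- .sixFrames(amplicon)
      if (length(frames)) {
        ph <- searchHits(prot, setNames(frames, paste0("frame", seq_along(frames))),
                         proteinScoring(), minScore = thresholds$minScoreProtein)
        if (nrow(ph)) found <- TRUE
      }
    }
  }
  list(gene_id = geneId, species_id = block$species_id,
       status = if (found) "CONTRADICTED" else "VALIDATED_ABSENT",
       ampliconWidth = wd, amplicon = as.character(amplicon))
}

#' Resolve all preliminary absences of an RBBH matrix
#'
#' Runs [flankingAnchors()], [locateBlock()], [rescueSearch()],
#' [classifyAbsence()] and [inSilicoValidation()] for every
#' `ABSENT_PRELIM` cell of a stage-1 matrix, producing the final
#' presence/absence matrix (caller `"rbbh_synteny"`).
#'
#' @param rbbhResult the list returned by [callMatrix()].
#' @param reference reference [AnnotatedGenome-class].
#' @param targets named list of target [AnnotatedGenome-class] objects.
#' @param thresholds see [orthologThresholds()].
#' @param k anchors per side.
#' @return a list: `matrix` (final [PresenceMatrix-class]), `calls`
#'   (data.frame of resolved absences with evidence), `validations`
#'   (data.frame of in-silico validation records), `blocks` (list of
#'   located blocks keyed `gene|species`).
#' @export
resolveAbsences <- function(rbbhResult, reference, targets,
                            thresholds = orthologThresholds(), k = 3) {
  if (is.null(names(targets)))
    names(targets) <- vapply(targets, speciesId, character(1))
  m <- calls(rbbhResult$matrix)
  stage <- stageOf(rbbhResult$matrix)
  det <- rbbhResult$details
  callsOut <- list(); valsOut <- list(); blocks <- list()
  for (sp in colnames(m)) {
    if (!(sp %in% names(targets))) next     # reference column
    idx <- rbbhResult$index[[sp]]
    target <- targets[[sp]]
    for (g in rownames(m)) {
      if (m[g, sp] != "ABSENT_PRELIM") next
      drow <- det[det$gene_id == g & det$species_id == sp, , drop = FALSE]
      prelim <- list(gene_id = g, species_id = sp, status = "ABSENT_PRELIM",
                     flag = if (nrow(drow)) drow$flag[1] else "")
      anchors <- flankingAnchors(g, reference, k = k)
      block <- locateBlock(anchors, target, reference, thresholds,
                           index = idx)
      rescue <- rescueSearch(g, block, reference, target, thresholds)
      cls <- classifyAbsence(prelim, block, rescue)
      m[g, sp] <- cls$status
      stage[g, sp] <- "synteny"
      blocks[[paste(g, sp, sep = "|")]] <- block
      callsOut[[length(callsOut) + 1L]] <- data.frame(
        gene_id = g, species_id = sp, status = cls$status,
        evidence = cls$evidence, stringsAsFactors = FALSE)
      if (cls$status %in% c("ABSENT_SYNTENY", "ABSENT_NO_SYNTENY")) {
        v <- inSilicoValidation(g, block, reference, target, thresholds)
        valsOut[[length(valsOut) + 1L]] <- data.frame(
          gene_id = g, species_id = sp, status = v$status,
          amplicon_width = v$ampliconWidth, stringsAsFactors = FALSE)
      }
    }
    .stageMsg("synteny %s: %d absence(s) resolved", sp,
              sum(det$species_id == sp & det$status == "ABSENT_PRELIM"))
  }
  final <- PresenceMatrix(m, caller = "rbbh_synteny", stage = stage)
  list(matrix = final,
       calls = if (length(callsOut)) do.call(rbind, callsOut) else NULL,
       validations = if (length(valsOut)) do.call(rbind, valsOut) else NULL,
       blocks = blocks)
}

#' Run the full two-stage ortholog pipeline
#'
#' Convenience wrapper: stage-1 RBBH matrix ([callMatrix()]) followed by
#' synteny-aware resolution of preliminary absences ([resolveAbsences()]).
#'
#' @inheritParams callMatrix
#' @param k anchors per side for the synteny stage.
#' @return a list: `prelim` (stage-1 [PresenceMatrix-class]), `final`
#'   (stage-2 matrix), `details` (stage-1 evidence), `resolution`
#'   (stage-2 calls/validations/blocks).
#' @examples
#' ref <- forgeReference(nGenes = 12, seed = 4)
#' phylo <- PhylogenyConfig("reference", c(reference = 0, spA = 10))
#' forged <- forgeClade(ref, phylo, seed = 4)
#' res <- runOrthologPipeline(geneIds(ref), ref, forged$genomes)
#' table(calls(res$final))
#' @export
runOrthologPipeline <- function(geneSet, reference, targets,
                                thresholds = orthologThresholds(),
                                scoring = proteinScoring(), k = 3) {
  rb <- callMatrix(geneSet, reference, targets, thresholds, scoring)
  rs <- resolveAbsences(rb, reference, targets, thresholds, k = k)
  list(prelim = rb$matrix, final = rs$matrix, details = rb$details,
       resolution = rs)
}
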