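## Synthetic-data forge: clades, fertility counts, codon sets -----------

.CODONS <- names(Biostrings::GENETIC_CODE)
.AAS <- setdiff(unique(Biostrings::GENETIC_CODE), "*")

# codon bookkeeping: synonymous alternatives, 1-nt neighbors by class,
# BLOSUM62-biased amino-acid replacement distributions
.codonTables <- function() {
  if (!is.null(.ot_cache$codonTables)) return(.ot_cache$codonTables)
  gc <- GENETIC_CODE
  aa2codons <- split(names(gc), gc)
  neighbors <- lapply(.CODONS, function(cod) {
    cc <- strsplit(cod, "")[[1]]
    out <- character()
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == cc[p]) next
      nb <- cc; nb[p] <- b
      out <- c(out, paste(nb, collapse = ""))
    }
    out
  })
  names(neighbors) <- .CODONS
  synNb <- lapply(.CODONS, function(cod) {
    nb <- neighbors[[cod]]
    nb[gc[nb] == gc[cod] & gc[nb] != "*"]
  })
  nonsynNb <- lapply(.CODONS, function(cod) {
    nb <- neighbors[[cod]]
    nb[gc[nb] != gc[cod] & gc[nb] != "*"]
  })
  names(synNb) <- names(nonsynNb) <- .CODONS
  b62 <- proteinScoring()$matrix
  aaSub <- lapply(.AAS, function(a) {
    others <- setdiff(.AAS, a)
    w <- exp(b62[a, others] / 2)
    w / sum(w)
  })
  names(aaSub) <- .AAS
  .ot_cache$codonTables <- list(aa2codons = aa2codons, neighbors = neighbors,
                                synNb = synNb, nonsynNb = nonsynNb,
                                aaSub = aaSub)
  .ot_cache$codonTables
}

.randomCodons <- function(n, pool = setdiff(.CODONS, names(GENETIC_CODE)[GENETIC_CODE == "*"])) {
  sample(pool, n, replace = TRUE)
}

.randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

.splitCodons <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))

#' Forge a random annotated reference genome
#'
#' Builds a toy but well-formed [AnnotatedGenome-class]: stop-free random
#' CDS genes laid out in order along contigs, separated by random
#' intergenic spacers, with a fraction of genes on the minus strand.
#' Serves as the root of [forgeClade()].
#'
#' @param nGenes total gene count (split evenly across contigs).
#' @param nContigs contig count.
#' @param geneCodons c(min, max) gene length range in codons.
#' @param spacer intergenic spacer length (bp).
#' @param minusFrac fraction of genes on the minus strand.
#' @param seed RNG seed.
#' @param speciesId species label.
#' @return an [AnnotatedGenome-class].
#' @export
forgeReference <- function(nGenes = 40, nContigs = 2,
                           geneCodons = c(100, 200), spacer = 250,
                           minusFrac = 0.3, seed = 1,
                           speciesId = "reference") {
  set.seed(seed)
  perContig <- diff(round(seq(0, nGenes, length.out = nContigs + 1)))
  contigSeqs <- character(nContigs)
  rows <- list()
  gidx <- 0L
  for (ci in seq_len(nContigs)) {
    cur <- .randomDNA(spacer)
    for (k in seq_len(perContig[ci])) {
      gidx <- gidx + 1L
      nc <- sample(seq(geneCodons[1], geneCodons[2]), 1)
      cds <- paste(.randomCodons(nc), collapse = "")
      strand <- if (runif(1) < minusFrac) "-" else "+"
      genomic <- if (strand == "-")
        as.character(reverseComplement(DNAString(cds))) else cds
      st <- nchar(cur) + 1L
      cur <- paste0(cur, genomic, .randomDNA(spacer))
      rows[[gidx]] <- data.frame(
        gene_id = sprintf("g%03d", gidx), contig = paste0("ctg", ci),
        start = st, end = st + nchar(genomic) - 1L, strand = strand,
        cds = cds, stringsAsFactors = FALSE)
    }
    contigSeqs[ci] <- cur
  }
  df <- do.call(rbind, rows)
  contigs <- DNAStringSet(setNames(contigSeqs, paste0("ctg", seq_len(nContigs))))
  gr <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$gene_id <- df$gene_id
  mcols(gr)$cds <- df$cds
  prot <- vapply(df$cds, function(s) {
    aa <- as.character(translate(DNAString(s)))
    sub("\\*$", "", aa)
  }, character(1), USE.NAMES = FALSE)
  mcols(gr)$protein <- prot
  mcols(gr)$untranslatable <- FALSE
  AnnotatedGenome(speciesId, contigs, gr)
}

# mutate a coding sequence codon-wise: amino-acid substitutions at pAa with
# a BLOSUM62 exchangeability bias, synonymous codon swaps at pSyn, optional
# whole-codon indels at pIndel (keeps frame)
.mutateCDS <- function(cdsChr, pAa, pSyn, pIndel = 0) {
  tb <- .codonTables()
  codons <- .splitCodons(cdsChr)
  out <- character(0)
  for (cod in codons) {
    aa <- GENETIC_CODE[[cod]]
    newCod <- cod
    if (runif(1) < pAa) {
      probs <- tb$aaSub[[aa]]
      newAa <- sample(names(probs), 1, prob = probs)
      newCod <- sample(tb$aa2codons[[newAa]], 1)
    } else if (runif(1) < pSyn) {
      alt <- setdiff(tb$aa2codons[[aa]], cod)
      if (length(alt)) newCod <- sample(alt, 1)
    }
    if (pIndel > 0 && runif(1) < pIndel) {
      if (runif(1) < 0.5) next                 # codon deletion
      out <- c(out, newCod)                    # codon duplication
    }
    out <- c(out, newCod)
  }
  if (!length(out)) out <- codons[1]
  paste(out, collapse = "")
}

# heavy nonsynonymous divergence with minimal nucleotide change: one-step
# nonsynonymous codon replacements at rate pAa (protein identity collapses,
# nucleotide identity stays ~1 - pAa/3)
.extremeCDS <- function(cdsChr, pAa = 0.8) {
  tb <- .codonTables()
  codons <- .splitCodons(cdsChr)
  for (i in seq_along(codons)) {
    if (runif(1) < pAa) {
      nb <- tb$nonsynNb[[codons[i]]]
      if (length(nb)) codons[i] <- sample(nb, 1)
    }
  }
  paste(codons, collapse = "")
}

.mutateDNA <- function(seqChr, p) {
  if (nchar(seqChr) == 0L || p <= 0) return(seqChr)
  cc <- strsplit(seqChr, "")[[1]]
  hit <- runif(length(cc)) < p
  if (any(hit)) {
    cc[hit] <- vapply(cc[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(cc, collapse = "")
}

.EVENTS <- c("conserved", "lost", "split_across_contigs", "at_contig_end",
             "diverged_extreme")
.EXPECTED_CALL <- c(conserved = "PRESENT_RBBH", lost = "ABSENT_SYNTENY",
                    split_across_contigs = "PRESENT_RESCUED",
                    at_contig_end = "UNRESOLVED_CONTIG_END",
                    diverged_extreme = "PRESENT_RESCUED")

#' Forge a clade of annotated genomes with known ortholog truth
#'
#' Derives one genome per non-reference species in `phylo` from a reference
#' [AnnotatedGenome-class].  Conserved genes are mutated toward an expected
#' protein identity `exp(-aaRatePerMy * divergence)` (amino-acid
#' substitutions with a BLOSUM62 exchangeability bias; synonymous-site
#' changes at three times the amino-acid-changing rate; intergenic
#' sequence mutated at the synonymous-scale rate), with gene order
#' preserved except where planted events dictate:
#'
#' * `lost` -- the gene body plus 50 bp margins is excised cleanly, flanks
#'   left adjacent (expected final call `ABSENT_SYNTENY`);
#' * `split_across_contigs` -- the CDS is cut mid-gene onto two contigs and
#'   left unannotated, modelling an assembly break inside the locus
#'   (expected `PRESENT_RESCUED`);
#' * `at_contig_end` -- the contig is truncated inside the gene and the
#'   distal half is dropped, so only a partial, unannotated locus survives
#'   at a contig edge (expected `UNRESOLVED_CONTIG_END`);
#' * `diverged_extreme` -- one-step nonsynonymous replacements collapse
#'   protein identity (~20%) while nucleotide identity stays high; the
#'   locus is left unannotated, modelling annotation failure on extreme
#'   divergence (expected `PRESENT_RESCUED` via the nucleotide route).
#'
#' @param reference the reference [AnnotatedGenome-class].
#' @param phylo a [PhylogenyConfig-class]; every non-reference species gets
#'   a genome.
#' @param divergence list: `aaRatePerMy` (amino-acid substitutions per site
#'   per MY, default 0.002) and `indelRate` (whole-codon indel probability
#'   per codon, default 0).
#' @param events `NULL` or a data.frame with columns `gene_id`,
#'   `species_id`, `event` (one of `r paste(.EVENTS, collapse=", ")`).
#' @param seed RNG seed; same seed gives byte-identical output.
#' @return a list: `genomes` (named list of [AnnotatedGenome-class]),
#'   `truth` (data.frame `gene_id`, `species_id`, `event`,
#'   `expected_call` covering every gene x species).
#' @examples
#' ref <- forgeReference(nGenes = 10, seed = 5)
#' phylo <- PhylogenyConfig("reference", c(reference = 0, spA = 20))
#' ev <- data.frame(gene_id = "g005", species_id = "spA", event = "lost")
#' fc <- forgeClade(ref, phylo, events = ev, seed = 5)
#' setdiff(geneIds(ref), sub("spA_", "", geneIds(fc$genomes$spA)))
#' @export
forgeClade <- function(reference, phylo,
                       divergence = list(aaRatePerMy = 0.002, indelRate = 0),
                       events = NULL, seed = 1) {
  speciesIds <- setdiff(names(divergenceMy(phylo)), referenceSpecies(phylo))
  ids <- geneIds(reference)
  if (!is.null(events)) {
    stopifnot(all(c("gene_id", "species_id", "event") %in% names(events)))
    if (!all(events$event %in% .EVENTS))
      stop("unknown event type(s): ",
           paste(setdiff(events$event, .EVENTS), collapse = ", "))
    if (!all(events$gene_id %in% ids)) stop("event gene not in reference")
    if (!all(events$species_id %in% speciesIds)) stop("event species not in clade")
    if (anyDuplicated(events[, c("gene_id", "species_id")]))
      stop("more than one event per (gene, species)")
  }
  aaRate <- divergence$aaRatePerMy %||% 0.002
  indelRate <- divergence$indelRate %||% 0

  truth <- expand.grid(gene_id = ids, species_id = speciesIds,
                       stringsAsFactors = FALSE)
  truth$event <- "conserved"
  if (!is.null(events) && nrow(events)) {
    key <- paste(truth$gene_id, truth$species_id)
    ekey <- paste(events$gene_id, events$species_id)
    truth$event[match(ekey, key)] <- events$event
  }
  truth$expected_call <- unname(.EXPECTED_CALL[truth$event])

  genomes <- list()
  for (si in seq_along(speciesIds)) {
    sp <- speciesIds[si]
    d <- divergenceMy(phylo)[[sp]]
    targetIdentity <- exp(-aaRate * d)
    if (targetIdentity < 0.05)
      stop("requested protein identity below 0.05 for species ", sp,
           "; refusing an un-testable regime")
    set.seed(.deriveSeed(seed, si))
    genomes[[sp]] <- .forgeSpecies(reference, sp, truth,
                                   pAa = 1 - targetIdentity,
                                   indelRate = indelRate)
    .stageMsg("forged %s at %g MY (target identity %.2f): %d contig(s), %d gene(s)",
              sp, d, targetIdentity, length(contigs(genomes[[sp]])),
              length(genes(genomes[[sp]])))
  }
  list(genomes = genomes, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.forgeSpecies <- function(reference, sp, truth, pAa, indelRate,
                          lossMargin = 50L) {
  pSyn <- min(1, 3 * pAa)
  pNt <- min(0.5, 3 * pAa)
  gr <- genes(reference)
  refContigs <- contigs(reference)
  ev <- truth[truth$species_id == sp, ]
  evMap <- setNames(ev$event, ev$gene_id)

  outContigs <- character(); outNames <- character()
  rows <- list()
  for (refCtg in names(refContigs)) {
    onCtg <- which(as.character(seqnames(gr)) == refCtg)
    refSeq <- refContigs[[refCtg]]
    part <- 1L
    cur <- ""
    closeContig <- function() {
      if (nchar(cur) > 0L) {
        outContigs <<- c(outContigs, cur)
        outNames <<- c(outNames, paste0(sp, "_", refCtg, "_p", part))
        part <<- part + 1L
        cur <<- ""
      }
    }
    prevEnd <- 0L
    prevLost <- FALSE
    for (i in onCtg) {
      gid <- mcols(gr)$gene_id[i]
      event <- evMap[[gid]] %||% "conserved"
      # intergenic segment before this gene, mutated; 50 bp margins are
      # excised next to a lost gene body
      ig <- if (start(gr)[i] - 1L >= prevEnd + 1L)
        as.character(subseq(refSeq, prevEnd + 1L, start(gr)[i] - 1L)) else ""
      ig <- .mutateDNA(ig, pNt)
      if (prevLost && nchar(ig) > 0L)
        ig <- substr(ig, min(nchar(ig), lossMargin) + 1L, nchar(ig))
      if (event == "lost" && nchar(ig) > 0L)
        ig <- substr(ig, 1L, max(0L, nchar(ig) - lossMargin))
      cur <- paste0(cur, ig)
      prevLost <- FALSE

      cdsRef <- mcols(gr)$cds[i]
      strand <- as.character(strand(gr))[i]
      asGenomic <- function(cdsChr) {
        if (strand == "-")
          as.character(reverseComplement(DNAString(cdsChr))) else cdsChr
      }
      if (event == "conserved") {
        cdsMut <- .mutateCDS(cdsRef, pAa, pSyn, indelRate)
        genomic <- asGenomic(cdsMut)
        st <- nchar(cur) + 1L
        cur <- paste0(cur, genomic)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = paste0(sp, "_", gid),
          contig = paste0(sp, "_", refCtg, "_p", part),
          start = st, end = st + nchar(genomic) - 1L, strand = strand,
          cds = cdsMut, stringsAsFactors = FALSE)
      } else if (event == "lost") {
        prevLost <- TRUE
      } else if (event %in% c("split_across_contigs", "at_contig_end")) {
        cdsMut <- .mutateCDS(cdsRef, pAa, pSyn, 0)
        genomic <- asGenomic(cdsMut)
        cut <- nchar(genomic) %/% 2L
        cur <- paste0(cur, substr(genomic, 1L, cut))
        closeContig()
        if (event == "split_across_contigs")
          cur <- paste0(cur, substr(genomic, cut + 1L, nchar(genomic)))
        # at_contig_end: distal half lost to the assembly gap
      } else if (event == "diverged_extreme") {
        cdsMut <- .extremeCDS(cdsRef)
        cur <- paste0(cur, asGenomic(cdsMut))   # present but unannotated
      }
      prevEnd <- end(gr)[i]
    }
    if (prevEnd < length(refSeq)) {
      ig <- .mutateDNA(as.character(subseq(refSeq, prevEnd + 1L, length(refSeq))), pNt)
      if (prevLost && nchar(ig) > 0L)
        ig <- substr(ig, min(nchar(ig), lossMargin) + 1L, nchar(ig))
      cur <- paste0(cur, ig)
    }
    closeContig()
  }
  contigSet <- DNAStringSet(setNames(outContigs, outNames))
  if (!length(rows)) {
    g <- GRanges()
    mcols(g)$gene_id <- character(); mcols(g)$cds <- character()
    mcols(g)$protein <- character(); mcols(g)$untranslatable <- logical()
    return(AnnotatedGenome(sp, contigSet, g))
  }
  df <- do.call(rbind, rows)
  g <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand)
  mcols(g)$gene_id <- df$gene_id
  mcols(g)$cds <- df$cds
  mcols(g)$protein <- vapply(df$cds, function(s)
    sub("\\*$", "", as.character(translate(DNAString(s)))),
    character(1), USE.NAMES = FALSE)
  mcols(g)$untranslatable <- FALSE
  AnnotatedGenome(sp, contigSet, g)
}

#' Write a forged clade to disk
#'
#' One FASTA + GFF3 per genome, plus the truth ledger as TSV.
#'
#' @param forged the list returned by [forgeClade()].
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
writeClade <- function(forged, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(forged$genomes))
    writeAnnotatedGenome(forged$genomes[[sp]],
                         file.path(dir, paste0(sp, ".fa")),
                         file.path(dir, paste0(sp, ".gff3")))
  write.table(forged$truth, file.path(dir, "truth_ledger.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate fertility-assay progeny counts
#'
#' Per-fly adult progeny counts per genotype, drawn negative-binomial
#' (overdispersed, the standard model for such counts); a `"sterile"`
#' genotype yields all-zero counts (complete sterility).  The function is
#' deterministic in `seed`.
#'
#' @param groups named list; each element either the string `"sterile"` or
#'   a list with `mean` and `dispersion` (NB size parameter, > 0).
#' @param n flies per genotype (>= 2).
#' @param seed RNG seed.
#' @return a data.frame: `fly_id`, `genotype`, `progeny`.
#' @examples
#' fd <- simulateFertility(list(wildtype = list(mean = 50, dispersion = 5),
#'                              null = "sterile"), n = 20, seed = 7)
#' tapply(fd$progeny, fd$genotype, mean)
#' @export
simulateFertility <- function(groups, n = 20, seed = 1) {
  if (n < 2) stop("need n >= 2 per group")
  if (length(groups) < 2) stop("need >= 2 genotypes")
  set.seed(seed)
  out <- list()
  for (gname in names(groups)) {
    gp <- groups[[gname]]
    counts <- if (identical(gp, "sterile")) {
      rep(0L, n)
    } else {
      if (is.null(gp$mean) || is.null(gp$dispersion))
        stop("group '", gname, "' needs mean and dispersion (or \"sterile\")")
      if (gp$dispersion <= 0) stop("dispersion must be > 0")
      rnbinom(n, size = gp$dispersion, mu = gp$mean)
    }
    out[[gname]] <- data.frame(
      fly_id = sprintf("%s_%02d", gname, seq_len(n)),
      genotype = gname, progeny = as.integer(counts),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a codon alignment with planted change counts
#'
#' Builds a [CodonAlignment-class] whose Dn/Ds/Pn/Ps truth is known by
#' construction: a stop-free random ancestor, `nIngroup` descendant copies,
#' and planted one-step codon changes -- fixed changes applied to every
#' ingroup sequence, polymorphic changes applied to `freq * nIngroup`
#' copies (minor-allele frequency).  Running [tabulateChanges()] +
#' [buildMKT()] with frequency cutoff 0 recovers the planted table
#' exactly.
#'
#' @param nCodons ancestor length in codons.
#' @param nIngroup number of ingroup sequences.
#' @param planted list with integer `fixedNonsyn`, `fixedSyn` and numeric
#'   frequency vectors `polyNonsyn`, `polySyn` (one planted polymorphism
#'   per element; each frequency must equal k/nIngroup for an integer
#'   1 <= k <= nIngroup/2).
#' @param seed RNG seed.
#' @return a list: `alignment` ([CodonAlignment-class]), `truth`
#'   (data.frame of planted changes), `counts` (named Dn/Ds/Pn/Ps).
#' @examples
#' sim <- simulateCodonSet(60, 10,
#'   planted = list(fixedNonsyn = 5, fixedSyn = 10,
#'                  polyNonsyn = rep(0.5, 4), polySyn = rep(0.5, 8)),
#'   seed = 11)
#' sim$counts
#' @export
simulateCodonSet <- function(nCodons, nIngroup,
                             planted = list(fixedNonsyn = 0, fixedSyn = 0,
                                            polyNonsyn = numeric(),
                                            polySyn = numeric()),
                             seed = 1) {
  tb <- .codonTables()
  fixedNonsyn <- planted$fixedNonsyn %||% 0
  fixedSyn <- planted$fixedSyn %||% 0
  polyNonsyn <- planted$polyNonsyn %||% numeric()
  polySyn <- planted$polySyn %||% numeric()
  total <- fixedNonsyn + fixedSyn + length(polyNonsyn) + length(polySyn)
  if (total > nCodons) stop("planted counts exceed codon count")
  for (f in c(polyNonsyn, polySyn)) {
    k <- f * nIngroup
    if (abs(k - round(k)) > 1e-9 || round(k) < 1 || round(k) > nIngroup / 2)
      stop("frequency ", f, " not representable as k/", nIngroup,
           " with k <= n/2")
  }
  set.seed(seed)
  # ancestor codons restricted to those with both change types available
  pool <- .CODONS[vapply(.CODONS, function(cod)
    GENETIC_CODE[[cod]] != "*" && length(tb$synNb[[cod]]) > 0 &&
      length(tb$nonsynNb[[cod]]) > 0, logical(1))]
  ancCodons <- sample(pool, nCodons, replace = TRUE)
  ingroup <- matrix(rep(ancCodons, nIngroup), nrow = nIngroup, byrow = TRUE)
  pos <- if (total > 0) sample(nCodons, total) else integer()
  trCodon <- integer(total); trKind <- character(total)
  trClass <- character(total); trFreq <- numeric(total)
  trFrom <- character(total); trTo <- character(total)
  cursor <- 0L
  plant <- function(kind, class, count, freqs = NULL) {
    for (j in seq_len(count)) {
      cursor <<- cursor + 1L
      p <- pos[cursor]
      nb <- if (class == "nonsynonymous") tb$nonsynNb[[ancCodons[p]]]
            else tb$synNb[[ancCodons[p]]]
      newCod <- nb[sample.int(length(nb), 1)]
      if (kind == "fixed") {
        ingroup[, p] <<- newCod
        f <- NA_real_
      } else {
        k <- round(freqs[j] * nIngroup)
        carriers <- sample(nIngroup, k)
        ingroup[carriers, p] <<- newCod
        f <- k / nIngroup
      }
      trCodon[cursor] <<- p; trKind[cursor] <<- kind
      trClass[cursor] <<- class; trFreq[cursor] <<- f
      trFrom[cursor] <<- ancCodons[p]; trTo[cursor] <<- newCod
    }
  }
  plant("fixed", "nonsynonymous", fixedNonsyn)
  plant("fixed", "synonymous", fixedSyn)
  plant("polymorphic", "nonsynonymous", length(polyNonsyn), polyNonsyn)
  plant("polymorphic", "synonymous", length(polySyn), polySyn)

  ingroupSeqs <- DNAStringSet(apply(ingroup, 1, paste, collapse = ""))
  names(ingroupSeqs) <- sprintf("ingroup_%02d", seq_len(nIngroup))
  anc <- DNAStringSet(setNames(paste(ancCodons, collapse = ""), "ancestor"))
  outg <- DNAStringSet(setNames(paste(ancCodons, collapse = ""), "outgroup"))
  truthDf <- data.frame(codon = trCodon, kind = trKind, class = trClass,
                        freq = trFreq, from = trFrom, to = trTo,
                        stringsAsFactors = FALSE)
  counts <- c(Dn = fixedNonsyn, Ds = fixedSyn,
              Pn = length(polyNonsyn), Ps = length(polySyn))
  list(alignment = CodonAlignment(ingroupSeqs, anc, outg),
       truth = truthDf, counts = counts)
}
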