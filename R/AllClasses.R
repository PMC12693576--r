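## Central S4 classes ---------------------------------------------------

#' AnnotatedGenome: contig sequences plus ordered gene models
#'
#' Container for one species' assembly: the contig sequences and an ordered
#' set of gene models.  Gene models live in a [GenomicRanges::GRanges]
#' (1-based inclusive coordinates, the Bioconductor convention) whose
#' metadata columns carry, per gene: `gene_id`, the spliced coding-strand
#' CDS (`cds`), the representative protein (`protein`, longest CDS per
#' gene), an `untranslatable` flag (CDS length not a multiple of three or
#' internal stop codon; such genes are excluded from protein search but
#' retained for nucleotide search), and `cdsParts`, an
#' [IRanges::IRangesList] of the genomic CDS segments so multi-exon
#' structure round-trips through GFF3 exactly.
#'
#' @slot speciesId single character species identifier.
#' @slot contigs [Biostrings::DNAStringSet] of contig sequences.
#' @slot genes [GenomicRanges::GRanges] of gene spans, sorted by contig
#'   (in `contigs` order) then start, with the metadata columns above.
#'
#' @seealso [readAnnotatedGenome()], [forgeReference()], [forgeClade()]
#' @export
setClass("AnnotatedGenome",
  representation(speciesId = "character",
                 contigs   = "DNAStringSet",
                 genes     = "GRanges"))

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  if (length(object@speciesId) != 1L || is.na(object@speciesId))
    msg <- c(msg, "speciesId must be a single non-NA string")
  gr <- object@genes
  need <- c("gene_id", "cds", "protein", "untranslatable")
  if (!all(need %in% names(mcols(gr))))
    msg <- c(msg, paste("genes must carry mcols:", paste(need, collapse = ", ")))
  else {
    ids <- mcols(gr)$gene_id
    if (anyDuplicated(ids)) msg <- c(msg, "gene_ids must be unique")
    cn <- names(object@contigs)
    sq <- as.character(seqnames(gr))
    if (!all(sq %in% cn))
      msg <- c(msg, "every gene contig_id must exist in contigs")
    else {
      w <- setNames(width(object@contigs), cn)
      if (any(start(gr) < 1L) || any(end(gr) > w[sq]))
        msg <- c(msg, "gene spans must lie within contig bounds")
    }
    # sorted by contig (contigs order), then start
    o <- order(match(sq, cn), start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "genes must be sorted by contig then start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param speciesId single character identifier.
#' @param contigs named [Biostrings::DNAStringSet].
#' @param genes [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `cds`, `protein`, `untranslatable` (and optionally `cdsParts`); it is
#'   sorted by contig then start on construction.
#' @return an [AnnotatedGenome-class] object.
#' @examples
#' ag <- forgeReference(nGenes = 6, seed = 1)
#' ag
#' @export
AnnotatedGenome <- function(speciesId, contigs, genes) {
  if (!"cdsParts" %in% names(mcols(genes)))
    mcols(genes)$cdsParts <- IRangesList(lapply(seq_along(genes), function(i)
      IRanges(start(genes)[i], end(genes)[i])))
  o <- order(match(as.character(seqnames(genes)), names(contigs)), start(genes))
  genes <- genes[o]
  seqlevels(genes) <- names(contigs)
  seqlengths(genes) <- width(contigs)
  new("AnnotatedGenome", speciesId = speciesId, contigs = contigs,
      genes = genes)
}

#' PhylogenyConfig: species divergence times from the reference
#'
#' @slot referenceSpecies the reference species id (divergence 0).
#' @slot divergenceMy named numeric, million years since divergence from the
#'   reference, per species; the reference maps to 0.
#' @slot cladeTree optional Newick string ("" when absent).
#' @seealso [loadPhylogenyConfig()]
#' @export
setClass("PhylogenyConfig",
  representation(referenceSpecies = "character",
                 divergenceMy     = "numeric",
                 cladeTree        = "character"))

setValidity("PhylogenyConfig", function(object) {
  d <- object@divergenceMy
  msg <- character()
  if (is.null(names(d)) || anyDuplicated(names(d)))
    msg <- c(msg, "divergenceMy must be uniquely named by species")
  if (!(object@referenceSpecies %in% names(d)))
    msg <- c(msg, "reference species missing from divergenceMy")
  else if (d[[object@referenceSpecies]] != 0)
    msg <- c(msg, "reference species must have divergence 0")
  if (any(d < 0)) msg <- c(msg, "divergence times must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhylogenyConfig
#'
#' @param referenceSpecies reference species id.
#' @param divergenceMy named numeric vector of divergence times (MY).
#' @param cladeTree optional Newick string.
#' @return a [PhylogenyConfig-class].
#' @examples
#' PhylogenyConfig("mel", c(mel = 0, simulans = 5, americana = 70))
#' @export
PhylogenyConfig <- function(referenceSpecies, divergenceMy, cladeTree = "") {
  new("PhylogenyConfig", referenceSpecies = referenceSpecies,
      divergenceMy = divergenceMy, cladeTree = cladeTree)
}

#' PresenceMatrix: gene-by-species grid of ortholog calls
#'
#' Complete genes x species character matrix over the call vocabulary (see
#' [isPresentCall()]), with a parallel `stage` matrix recording which
#' pipeline stage produced each cell and a `caller` label identifying the
#' strategy (`"rbbh"`, `"rbbh_synteny"`, `"naive"`, `"ensembl_import"`).
#'
#' @slot calls character matrix, rownames = gene ids, colnames = species.
#' @slot stage character matrix, same shape, per-cell provenance.
#' @slot caller single character strategy label.
#' @seealso [callMatrix()], [resolveAbsences()], [perSpeciesSummary()]
#' @export
setClass("PresenceMatrix",
  representation(calls = "matrix", stage = "matrix", caller = "character"))

setValidity("PresenceMatrix", function(object) {
  m <- object@calls
  msg <- character()
  if (!is.character(m) || is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "calls must be a character matrix with dimnames")
  if (anyNA(m)) msg <- c(msg, "matrix must be complete (no missing cells)")
  bad <- setdiff(unique(as.vector(m)), .CALL_LEVELS)
  if (length(bad))
    msg <- c(msg, paste("unknown call token(s):", paste(bad, collapse = ", ")))
  if (!identical(dim(object@stage), dim(m)))
    msg <- c(msg, "stage matrix must match calls in shape")
  if (length(object@caller) != 1L)
    msg <- c(msg, "caller must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#'
#' @param calls character matrix of call tokens (genes x species, dimnames
#'   required).
#' @param caller strategy label.
#' @param stage optional per-cell provenance matrix; defaults to `caller`
#'   everywhere.
#' @return a [PresenceMatrix-class].
#' @export
PresenceMatrix <- function(calls, caller, stage = NULL) {
  if (is.null(stage)) {
    stage <- matrix(caller, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  }
  new("PresenceMatrix", calls = calls, stage = stage, caller = caller)
}

#' CodonAlignment: in-frame alignment of ingroup, ancestor and outgroup
#'
#' Equal-length, in-frame aligned sequences: `n` ingroup sequences (the
#' polymorphism sample), one ancestor (common ancestor of the focal and
#' sister lineages, used to polarize lineage-specific divergence), and an
#' optional outgroup.  Gaps must come in whole-codon units; codon columns
#' containing gaps or ambiguity in any used sequence are excluded during
#' tabulation and reported.
#'
#' @slot ingroup [Biostrings::DNAStringSet] of n aligned sequences.
#' @slot ancestor [Biostrings::DNAStringSet] of length 1.
#' @slot outgroup [Biostrings::DNAStringSet] of length 0 or 1.
#' @seealso [tabulateChanges()], [mktTest()], [simulateCodonSet()]
#' @export
setClass("CodonAlignment",
  representation(ingroup = "DNAStringSet", ancestor = "DNAStringSet",
                 outgroup = "DNAStringSet"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  ws <- c(width(object@ingroup), width(object@ancestor), width(object@outgroup))
  if (length(object@ancestor) != 1L)
    msg <- c(msg, "exactly one ancestor sequence required")
  if (length(object@ingroup) < 2L)
    msg <- c(msg, "at least two ingroup sequences required")
  if (length(unique(ws)) > 1L)
    msg <- c(msg, "all sequences must have equal aligned length")
  if (length(ws) && ws[1] %% 3L != 0L)
    msg <- c(msg, "aligned length must be divisible by 3")
  if (length(object@ancestor) == 1L) {
    anc <- as.character(object@ancestor[[1]])
    cod <- substring(anc, seq(1, nchar(anc), 3), seq(3, nchar(anc), 3))
    cod <- cod[!grepl("[-N]", cod)]
    if (any(GENETIC_CODE[cod] == "*", na.rm = TRUE))
      msg <- c(msg, "ancestor contains an internal stop codon")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CodonAlignment
#'
#' @param ingroup,ancestor,outgroup [Biostrings::DNAStringSet] (or coercible)
#'   aligned in-frame sequences; `outgroup` may be omitted.
#' @return a [CodonAlignment-class].
#' @export
CodonAlignment <- function(ingroup, ancestor, outgroup = DNAStringSet()) {
  new("CodonAlignment", ingroup = as(ingroup, "DNAStringSet"),
      ancestor = as(ancestor, "DNAStringSet"),
      outgroup = as(outgroup, "DNAStringSet"))
}

#' MKTResult: McDonald-Kreitman 2x2 table with NI and alpha
#'
#' Holds the (possibly fractional, pathway-averaged) Dn/Ds/Pn/Ps counts,
#' the integer-rounded table actually submitted to the Fisher test, the
#' polymorphism frequency cutoff applied, the two-tailed Fisher p-value,
#' the neutrality index NI = (Pn/Ps)/(Dn/Ds) and alpha = 1 - NI (both `NA`
#' when a denominator is zero), and exclusion bookkeeping.
#'
#' @slot counts named numeric `(Dn, Ds, Pn, Ps)`, fractional allowed.
#' @slot countsRounded named integer table used for the Fisher test.
#' @slot freqCutoff minor-allele-frequency cutoff applied (strict `<`).
#' @slot pValue two-tailed Fisher exact p.
#' @slot ni,alpha neutrality index and alpha (`NA` when undefined).
#' @slot nExcludedCodons codon columns dropped for gaps/ambiguity/stops.
#' @slot nFilteredPoly polymorphic changes removed by the frequency filter.
#' @seealso [buildMKT()], [mktTest()]
#' @export
setClass("MKTResult",
  representation(counts = "numeric", countsRounded = "integer",
                 freqCutoff = "numeric", pValue = "numeric",
                 ni = "numeric", alpha = "numeric",
                 nExcludedCodons = "integer", nFilteredPoly = "integer"))
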