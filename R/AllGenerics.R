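## Generics and accessors -----------------------------------------------

#' @describeIn AnnotatedGenome species identifier
#' @param object,x an object.
#' @export
setGeneric("speciesId", function(object) standardGeneric("speciesId"))
#' @export
setMethod("speciesId", "AnnotatedGenome", function(object) object@speciesId)

#' @describeIn AnnotatedGenome contig sequences
#' @export
setGeneric("contigs", function(object) standardGeneric("contigs"))
#' @export
setMethod("contigs", "AnnotatedGenome", function(object) object@contigs)

#' @describeIn AnnotatedGenome gene models as a GRanges
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))
#' @export
setMethod("genes", "AnnotatedGenome", function(object) object@genes)

#' @describeIn AnnotatedGenome gene identifiers in genome order
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @export
setMethod("geneIds", "AnnotatedGenome", function(object) mcols(object@genes)$gene_id)

#' @describeIn AnnotatedGenome representative proteins (one per translatable
#'   gene) as a named AAStringSet
#' @export
setGeneric("proteome", function(object) standardGeneric("proteome"))
#' @export
setMethod("proteome", "AnnotatedGenome", function(object) {
  mc <- mcols(object@genes)
  keep <- !mc$untranslatable
  AAStringSet(setNames(mc$protein[keep], mc$gene_id[keep]))
})

#' @describeIn AnnotatedGenome spliced coding-strand CDS sequences as a
#'   named DNAStringSet
#' @export
setGeneric("cdsSeqs", function(object) standardGeneric("cdsSeqs"))
#' @export
setMethod("cdsSeqs", "AnnotatedGenome", function(object) {
  mc <- mcols(object@genes)
  DNAStringSet(setNames(mc$cds, mc$gene_id))
})

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome '", object@speciesId, "': ",
      length(object@contigs), " contig(s), ",
      length(object@genes), " gene model(s) (",
      sum(mcols(object@genes)$untranslatable), " untranslatable)\n", sep = "")
})

#' @describeIn PresenceMatrix the call matrix
#' @param object,x an object.
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))
#' @export
setMethod("calls", "PresenceMatrix", function(object) object@calls)

#' @describeIn PresenceMatrix the strategy label
#' @export
setGeneric("caller", function(object) standardGeneric("caller"))
#' @export
setMethod("caller", "PresenceMatrix", function(object) object@caller)

#' @describeIn PresenceMatrix the per-cell provenance matrix
#' @export
setGeneric("stageOf", function(object) standardGeneric("stageOf"))
#' @export
setMethod("stageOf", "PresenceMatrix", function(object) object@stage)

#' @export
setMethod("dim", "PresenceMatrix", function(x) dim(x@calls))
#' @export
setMethod("dimnames", "PresenceMatrix", function(x) dimnames(x@calls))

setMethod("show", "PresenceMatrix", function(object) {
  m <- object@calls
  cat("PresenceMatrix [", nrow(m), " gene(s) x ", ncol(m), " species], caller='",
      object@caller, "'\n", sep = "")
  tab <- table(factor(as.vector(m), levels = .CALL_LEVELS))
  tab <- tab[tab > 0]
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
})

setMethod("show", "PhylogenyConfig", function(object) {
  cat("PhylogenyConfig: reference '", object@referenceSpecies, "', ",
      length(object@divergenceMy), " species, max divergence ",
      max(object@divergenceMy), " MY\n", sep = "")
})

#' @describeIn PhylogenyConfig named divergence times (MY)
#' @param object an object.
#' @export
setGeneric("divergenceMy", function(object) standardGeneric("divergenceMy"))
#' @export
setMethod("divergenceMy", "PhylogenyConfig", function(object) object@divergenceMy)

#' @describeIn PhylogenyConfig the reference species id
#' @export
setGeneric("referenceSpecies", function(object) standardGeneric("referenceSpecies"))
#' @export
setMethod("referenceSpecies", "PhylogenyConfig",
          function(object) object@referenceSpecies)

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment: ", length(object@ingroup), " ingroup seq(s), ",
      width(object@ancestor)[1] %/% 3L, " codons, outgroup: ",
      if (length(object@outgroup)) "yes" else "no", "\n", sep = "")
})

#' @describeIn MKTResult named fractional counts (Dn, Ds, Pn, Ps)
#' @param object an object.
#' @export
setGeneric("mktCounts", function(object) standardGeneric("mktCounts"))
#' @export
setMethod("mktCounts", "MKTResult", function(object) object@counts)

#' @describeIn MKTResult neutrality index (Pn/Ps)/(Dn/Ds), `NA` if undefined
#' @export
setGeneric("neutralityIndex", function(object) standardGeneric("neutralityIndex"))
#' @export
setMethod("neutralityIndex", "MKTResult", function(object) object@ni)

#' @describeIn MKTResult alpha = 1 - NI, `NA` if undefined
#' @export
setGeneric("mktAlpha", function(object) standardGeneric("mktAlpha"))
#' @export
setMethod("mktAlpha", "MKTResult", function(object) object@alpha)

#' @describeIn MKTResult two-tailed Fisher exact p-value
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @export
setMethod("pValue", "MKTResult", function(object) object@pValue)

setMethod("show", "MKTResult", function(object) {
  ct <- object@counts
  cat("McDonald-Kreitman test (freq cutoff ", object@freqCutoff, ")\n",
      sprintf("  Dn=%.3g Ds=%.3g Pn=%.3g Ps=%.3g\n",
              ct["Dn"], ct["Ds"], ct["Pn"], ct["Ps"]),
      sprintf("  NI=%s alpha=%s  Fisher two-tailed p=%.4g\n",
              format(object@ni, digits = 4), format(object@alpha, digits = 4),
              object@pValue), sep = "")
  if (object@nExcludedCodons > 0L)
    cat("  (", object@nExcludedCodons, " codon column(s) excluded)\n", sep = "")
})
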