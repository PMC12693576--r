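## Confidence tiering of final absences ---------------------------------

#' Tier final absences by evidential strength
#'
#' Every absent `(gene, species)` cell of a final presence matrix receives
#' a confidence tier: `VALIDATED` when an in-silico validation record
#' confirms the absence (`VALIDATED_ABSENT`); otherwise `HIGH` when the
#' gene has a present ortholog in a species at least as divergent from the
#' reference as the absence species (a deeper present witness argues for
#' real loss over detection failure); otherwise `LOW` (absences confined
#' to the deepest, most divergent lineages, where detection failure from
#' sheer sequence divergence cannot be excluded).  Precedence is
#' `VALIDATED > HIGH > LOW`; lineage support for validated absences is
#' noted in the rationale.  Because lineage support can be judged per
#' absence or per gene (any absent species of the gene), both are
#' reported: `tier` uses the per-absence rule and `gene_support` records
#' whether every absence of that gene has a deeper present witness.
#'
#' @param matrix a final [PresenceMatrix-class] (post-synteny).
#' @param phylo a [PhylogenyConfig-class] covering every matrix species.
#' @param validations optional data.frame with columns
#'   `gene_id`, `species_id`, `status` (from [resolveAbsences()]).
#' @return a data.frame: `gene_id`, `species_id`, `tier`, `gene_support`,
#'   `rationale`.
#' @examples
#' m <- matrix(c("PRESENT_REFERENCE", "ABSENT_SYNTENY", "PRESENT_RBBH"), 1, 3,
#'             dimnames = list("g1", c("ref", "mid", "deep")))
#' pm <- PresenceMatrix(m, "rbbh_synteny")
#' phylo <- PhylogenyConfig("ref", c(ref = 0, mid = 30, deep = 70))
#' tierAbsences(pm, phylo)$tier
#' @export
tierAbsences <- function(matrix, phylo, validations = NULL) {
  m <- calls(matrix)
  d <- divergenceMy(phylo)
  missingSp <- setdiff(colnames(m), names(d))
  if (length(missingSp))
    stop("species missing from phylogeny config: ",
         paste(missingSp, collapse = ", "))
  out <- list()
  for (g in rownames(m)) {
    absentSp <- colnames(m)[isAbsentCall(m[g, ])]
    if (!length(absentSp)) next
    presentDiv <- d[colnames(m)[isPresentCall(m[g, ])]]
    geneSupport <- length(absentSp) > 0 &&
      all(vapply(absentSp, function(s)
        any(presentDiv >= d[[s]]), logical(1)))
    for (s in absentSp) {
      validated <- FALSE
      if (!is.null(validations) && nrow(validations)) {
        v <- validations[validations$gene_id == g &
                           validations$species_id == s, , drop = FALSE]
        validated <- nrow(v) > 0 && any(v$status == "VALIDATED_ABSENT")
      }
      support <- any(presentDiv >= d[[s]])
      tier <- if (validated) "VALIDATED" else if (support) "HIGH" else "LOW"
      rationale <-
        if (validated && support)
          "absence validated in-silico; present witness at >= divergence"
        else if (validated) "absence validated in-silico"
        else if (support)
          sprintf("present ortholog at divergence >= %g MY", d[[s]])
        else "absence only in deepest lineages; no deeper present witness"
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, species_id = s, tier = tier,
        gene_support = geneSupport, rationale = rationale,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), species_id = character(),
                      tier = character(), gene_support = logical(),
                      rationale = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
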