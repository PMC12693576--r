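## Headline summaries and interaction-network co-absence ----------------

#' Per-species absence counts and percentages
#'
#' Counts absences per species over the focal gene total.
#' `UNRESOLVED_CONTIG_END` cells are conservatively not counted as absent
#' by default (switchable).
#'
#' @param matrix a [PresenceMatrix-class].
#' @param countUnresolved count `UNRESOLVED_CONTIG_END` as absent?
#' @return a data.frame: `species`, `n_absent`, `pct_absent` (percent of
#'   the focal gene count, 2 decimals).
#' @examples
#' m <- matrix(c("PRESENT_RBBH", "ABSENT_SYNTENY", "PRESENT_RBBH",
#'               "PRESENT_RBBH", "ABSENT_NO_SYNTENY", "ABSENT_SYNTENY"), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("spA", "spB")))
#' perSpeciesSummary(PresenceMatrix(m, "rbbh_synteny"))
#' @export
perSpeciesSummary <- function(matrix, countUnresolved = FALSE) {
  m <- calls(matrix)
  absent <- isAbsentCall(m)
  if (countUnresolved) absent <- absent | m == "UNRESOLVED_CONTIG_END"
  nA <- colSums(absent)
  data.frame(species = colnames(m), n_absent = unname(nA),
             pct_absent = unname(round(100 * nA / nrow(m), 2)),
             stringsAsFactors = FALSE)
}

#' Genes absent in at least one species
#'
#' @param matrix a [PresenceMatrix-class].
#' @param countUnresolved count `UNRESOLVED_CONTIG_END` as absent?
#' @return character vector of gene ids with at least one absent cell.
#' @export
anyAbsenceGenes <- function(matrix, countUnresolved = FALSE) {
  m <- calls(matrix)
  absent <- isAbsentCall(m)
  if (countUnresolved) absent <- absent | m == "UNRESOLVED_CONTIG_END"
  rownames(m)[rowSums(absent) > 0]
}

#' Absence breakdown by functional category and defect type
#'
#' A gene belonging to several functional categories counts once in each
#' (categories may overlap); percentages are genes-with-any-absence over
#' genes-in-category, to 2 decimals.
#'
#' @param matrix a [PresenceMatrix-class].
#' @param annotations data.frame with columns `gene_id`,
#'   `functional_category` (`;`-separated for multiple; `NA` or `""` maps
#'   to `"No functional category"`), `defect_type` (optional).
#' @param countUnresolved count `UNRESOLVED_CONTIG_END` as absent?
#' @return a list of two data.frames, `categories` and `defects`, each
#'   with `group`, `n_genes`, `n_with_absence`, `pct`.
#' @export
categorySummary <- function(matrix, annotations, countUnresolved = FALSE) {
  stopifnot(all(c("gene_id", "functional_category") %in% names(annotations)))
  genesAbs <- anyAbsenceGenes(matrix, countUnresolved)
  missing <- setdiff(rownames(calls(matrix)), annotations$gene_id)
  if (length(missing))
    stop("unannotated focal gene(s): ", paste(head(missing, 5), collapse = ", "))
  summarize <- function(col) {
    vals <- annotations[[col]]
    vals[is.na(vals) | vals == ""] <-
      if (col == "functional_category") "No functional category" else "Unspecified"
    tokens <- strsplit(vals, ";", fixed = TRUE)
    long <- data.frame(
      gene_id = rep(annotations$gene_id, lengths(tokens)),
      group = trimws(unlist(tokens)), stringsAsFactors = FALSE)
    long <- unique(long)
    spl <- split(long$gene_id, long$group)
    data.frame(
      group = names(spl),
      n_genes = lengths(spl),
      n_with_absence = vapply(spl, function(g) sum(g %in% genesAbs), 1L),
      pct = round(100 * vapply(spl, function(g) mean(g %in% genesAbs),
                               numeric(1)), 2),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- list(categories = summarize("functional_category"))
  if ("defect_type" %in% names(annotations))
    out$defects <- summarize("defect_type")
  out
}

#' Interaction-network co-absence statistics
#'
#' For every focal gene with at least one absence: its interaction-network
#' size, how many interactors are absent anywhere, and how many
#' interactor absences fall in the same species as an absence of the
#' focal gene.  Interactors without presence calls in the matrix are
#' counted `unevaluated` and excluded from denominators.
#'
#' @param matrix a [PresenceMatrix-class] whose rows include the evaluated
#'   interactors as well as the focal genes.
#' @param network data.frame with columns `gene_id`, `interactor_id`
#'   and optionally `kind` (`physical`/`genetic`); self-edges are dropped.
#' @param countUnresolved count `UNRESOLVED_CONTIG_END` as absent?
#' @return a list: `perGene` (data.frame `gene_id`, `network_size`,
#'   `n_evaluated`, `n_unevaluated`, `n_interactors_absent`,
#'   `n_coabsent_same_species`) and `global` (named numeric tallies:
#'   `n_absent_genes`, `n_with_interactions`, `n_with_network_absence`,
#'   `n_same_species_pairs`).
#' @export
networkCooccurrence <- function(matrix, network, countUnresolved = FALSE) {
  stopifnot(all(c("gene_id", "interactor_id") %in% names(network)))
  network <- network[network$gene_id != network$interactor_id, , drop = FALSE]
  m <- calls(matrix)
  absent <- isAbsentCall(m)
  if (countUnresolved) absent <- absent | m == "UNRESOLVED_CONTIG_END"
  focalAbs <- rownames(m)[rowSums(absent) > 0]
  rows <- list()
  for (g in focalAbs) {
    inter <- unique(network$interactor_id[network$gene_id == g])
    evaluated <- intersect(inter, rownames(m))
    unevaluated <- setdiff(inter, rownames(m))
    nAbsent <- 0L; nCo <- 0L
    gSpecies <- colnames(m)[absent[g, ]]
    for (it in evaluated) {
      itSpecies <- colnames(m)[absent[it, ]]
      if (length(itSpecies)) {
        nAbsent <- nAbsent + 1L
        nCo <- nCo + length(intersect(gSpecies, itSpecies))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, network_size = length(inter),
      n_evaluated = length(evaluated), n_unevaluated = length(unevaluated),
      n_interactors_absent = nAbsent, n_coabsent_same_species = nCo,
      stringsAsFactors = FALSE)
  }
  perGene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), network_size = integer(),
               n_evaluated = integer(), n_unevaluated = integer(),
               n_interactors_absent = integer(),
               n_coabsent_same_species = integer())
  global <- c(
    n_absent_genes = length(focalAbs),
    n_with_interactions = sum(perGene$network_size > 0),
    n_with_network_absence = sum(perGene$n_interactors_absent > 0),
    n_same_species_pairs = sum(perGene$n_coabsent_same_species))
  list(perGene = perGene, global = global)
}

#' Import external ortholog predictions as a presence matrix
#'
#' Converts a precomputed per-(gene, species) ortholog table (for example
#' an Ensembl-style export with alignment identities) into a
#' [PresenceMatrix-class] comparable with the RBBH callers: a prediction
#' counts as present only when its identity reaches `minIdentity`
#' (boundary inclusive); rows below it, and gene/species pairs missing
#' from the table, are absent.  Malformed rows (missing fields,
#' unparsable identity) are skipped with a count.
#'
#' @param table data.frame with columns `gene_id`, `species_id`,
#'   `identity` (percent, 0-100).
#' @param geneSet,speciesIds the full universes for the matrix (defaults:
#'   those seen in the table).
#' @param minIdentity identity fraction required (default 0.25).
#' @return a [PresenceMatrix-class] with caller `"ensembl_import"`.
#' @examples
#' tab <- data.frame(gene_id = c("g1", "g1"), species_id = c("spA", "spB"),
#'                   identity = c(24.9, 25))
#' calls(importExternalPredictions(tab))
#' @export
importExternalPredictions <- function(table, geneSet = NULL,
                                      speciesIds = NULL,
                                      minIdentity = 0.25) {
  stopifnot(all(c("gene_id", "species_id", "identity") %in% names(table)))
  idn <- suppressWarnings(as.numeric(table$identity))
  bad <- is.na(idn) | is.na(table$gene_id) | is.na(table$species_id) |
    table$gene_id == "" | table$species_id == ""
  if (any(bad))
    warning(sum(bad), " malformed row(s) skipped")
  tab <- table[!bad, , drop = FALSE]
  idn <- idn[!bad]
  if (is.null(geneSet)) geneSet <- unique(table$gene_id[!is.na(table$gene_id)])
  if (is.null(speciesIds))
    speciesIds <- unique(table$species_id[!is.na(table$species_id)])
  if (!length(geneSet) || !length(speciesIds))
    stop("empty gene or species universe")
  m <- matrix("ABSENT", length(geneSet), length(speciesIds),
              dimnames = list(geneSet, speciesIds))
  if (!nrow(tab)) warning("no usable predictions; all absent")
  keep <- idn / 100 >= minIdentity
  for (i in which(keep)) {
    g <- tab$gene_id[i]; s <- tab$species_id[i]
    if (g %in% geneSet && s %in% speciesIds) m[g, s] <- "PRESENT"
  }
  PresenceMatrix(m, caller = "ensembl_import")
}
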