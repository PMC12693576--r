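## Reading and writing annotated genomes, configs and matrices ----------

#' Read an annotated genome from FASTA + GFF3
#'
#' Builds an [AnnotatedGenome-class] from a contig FASTA and a GFF3 carrying
#' `gene`/`mRNA`/`CDS` features.  GFF3 1-based inclusive coordinates are kept
#' as-is internally (GRanges convention), so a GFF3 -> internal -> GFF3
#' round trip preserves coordinates exactly.  Minus-strand CDS are
#' reverse-complemented and phase-assembled into the coding-strand spliced
#' CDS; one representative protein per gene is chosen as the transcript with
#' the longest total CDS.  A CDS whose length is not a multiple of three, or
#' whose translation has an internal stop, is flagged `untranslatable` with
#' a warning (excluded from protein search, retained for nucleotide search).
#' A GFF3 record on a contig absent from the FASTA is a hard error.
#'
#' @param fastaPath path to the contig FASTA.
#' @param gff3Path path to the GFF3 annotation.
#' @param speciesId species identifier; defaults to the FASTA file stem.
#' @return an [AnnotatedGenome-class].
#' @examples
#' ag <- forgeReference(nGenes = 5, seed = 1)
#' dir <- tempfile(); dir.create(dir)
#' writeAnnotatedGenome(ag, file.path(dir, "ref.fa"), file.path(dir, "ref.gff3"))
#' ag2 <- readAnnotatedGenome(file.path(dir, "ref.fa"), file.path(dir, "ref.gff3"),
#'                            speciesId = "reference")
#' identical(geneIds(ag), geneIds(ag2))
#' @export
readAnnotatedGenome <- function(fastaPath, gff3Path,
                                speciesId = sub("\\.[^.]*$", "", basename(fastaPath))) {
  contigs <- readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*", "", names(contigs))
  gff <- import(gff3Path, format = "gff3")
  sq <- as.character(seqnames(gff))
  missingContig <- setdiff(unique(sq), names(contigs))
  if (length(missingContig))
    stop("GFF3 references contig(s) absent from FASTA: ",
         paste(missingContig, collapse = ", "))

  type <- as.character(gff$type)
  geneRows <- gff[type == "gene"]
  mrnaRows <- gff[type %in% c("mRNA", "transcript")]
  cdsRows  <- gff[type == "CDS"]
  if (!length(geneRows)) stop("GFF3 contains no gene features")
  firstParent <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrnaParent <- firstParent(mrnaRows)
  cdsParent  <- firstParent(cdsRows)

  ids <- geneRows$ID
  if (anyDuplicated(ids)) stop("duplicate gene IDs in GFF3")

  buildGene <- function(i) {
    gid <- ids[i]
    txIds <- mrnaRows$ID[mrnaParent == gid]
    segsBy <- lapply(txIds, function(tx) cdsRows[cdsParent == tx])
    direct <- cdsRows[cdsParent == gid]        # CDS parented by the gene
    if (length(direct)) segsBy <- c(segsBy, list(direct))
    segsBy <- segsBy[vapply(segsBy, length, 1L) > 0]
    if (!length(segsBy))
      return(list(cds = "", untranslatable = TRUE, protein = NA_character_,
                  parts = IRanges()))
    tot <- vapply(segsBy, function(s) sum(width(s)), numeric(1))
    segs <- segsBy[[which.max(tot)]]
    segs <- segs[order(start(segs))]
    pieces <- DNAStringSet(lapply(seq_along(segs), function(k)
      subseq(contigs[[as.character(seqnames(segs))[k]]],
             start(segs)[k], end(segs)[k])))
    cdsSeq <- do.call(xscat, as.list(pieces))
    minus <- as.character(strand(geneRows)[i]) == "-"
    if (minus) cdsSeq <- reverseComplement(cdsSeq)
    # phase of the translation-initial segment trims incomplete 5' codon
    ph <- segs$phase
    if (!is.null(ph) && length(ph)) {
      p0 <- if (minus) ph[length(ph)] else ph[1]
      p0 <- suppressWarnings(as.integer(as.character(p0)))
      if (!is.na(p0) && p0 > 0L) cdsSeq <- subseq(cdsSeq, p0 + 1L)
    }
    cdsChr <- as.character(cdsSeq)
    untr <- FALSE; prot <- NA_character_
    if (nchar(cdsChr) %% 3L != 0L) {
      warning("gene ", gid, ": CDS length not a multiple of 3; marked untranslatable")
      untr <- TRUE
    } else {
      aa <- as.character(suppressWarnings(translate(cdsSeq, if.fuzzy.codon = "solve")))
      if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1L)
      if (grepl("\\*", aa)) {
        warning("gene ", gid, ": internal stop codon; marked untranslatable")
        untr <- TRUE
      } else prot <- aa
    }
    list(cds = cdsChr, untranslatable = untr, protein = prot,
         parts = IRanges(start(segs), end(segs)))
  }

  built <- lapply(seq_along(geneRows), buildGene)
  gr <- GRanges(seqnames = as.character(seqnames(geneRows)),
                ranges = IRanges(start(geneRows), end(geneRows)),
                strand = strand(geneRows))
  mcols(gr)$gene_id <- ids
  mcols(gr)$cds <- vapply(built, `[[`, character(1), "cds")
  mcols(gr)$protein <- vapply(built, `[[`, character(1), "protein")
  mcols(gr)$untranslatable <- vapply(built, `[[`, logical(1), "untranslatable")
  mcols(gr)$cdsParts <- IRangesList(lapply(built, `[[`, "parts"))
  AnnotatedGenome(speciesId, contigs, gr)
}

#' Write an annotated genome to FASTA + GFF3
#'
#' Inverse of [readAnnotatedGenome()]: writes the contigs as FASTA and the
#' gene models as GFF3 `gene`/`mRNA`/`CDS` rows (1-based inclusive), using
#' the stored genomic CDS segments so coordinates round-trip exactly.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param fastaPath,gff3Path output paths.
#' @return invisibly, the two paths.
#' @export
writeAnnotatedGenome <- function(genome, fastaPath, gff3Path) {
  writeXStringSet(contigs(genome), fastaPath)
  gr <- genes(genome)
  rows <- list()
  for (i in seq_along(gr)) {
    gid <- mcols(gr)$gene_id[i]
    sq <- as.character(seqnames(gr))[i]
    st <- as.character(strand(gr))[i]
    parts <- mcols(gr)$cdsParts[[i]]
    tx <- paste0(gid, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      seq = sq, start = start(gr)[i], end = end(gr)[i], strand = st,
      type = "gene", ID = gid, Parent = NA_character_, phase = NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(
      seq = sq, start = min(start(parts)), end = max(end(parts)), strand = st,
      type = "mRNA", ID = tx, Parent = gid, phase = NA_integer_)
    for (k in seq_along(parts))
      rows[[length(rows) + 1L]] <- data.frame(
        seq = sq, start = start(parts)[k], end = end(parts)[k], strand = st,
        type = "CDS", ID = paste0(tx, ".cds", k), Parent = tx, phase = 0L)
  }
  df <- do.call(rbind, rows)
  out <- GRanges(df$seq, IRanges(df$start, df$end), strand = df$strand)
  mcols(out)$source <- "OrthoTrace"
  mcols(out)$type <- df$type
  mcols(out)$ID <- df$ID
  mcols(out)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  mcols(out)$phase <- df$phase
  export(out, gff3Path, format = "gff3")
  invisible(c(fastaPath, gff3Path))
}

#' Load a phylogeny configuration (divergence times) from TSV or JSON
#'
#' JSON format: an object with `reference_species`, `divergence_my` (map of
#' species to million years since divergence from the reference) and
#' optional `clade_tree` (Newick).  TSV format: columns `species` and
#' `divergence_my`; the reference is the unique species with divergence 0.
#' Errors on negative times, duplicate species, or a missing reference row.
#'
#' @param path path to a `.json` or `.tsv` file.
#' @return a [PhylogenyConfig-class].
#' @export
loadPhylogenyConfig <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- fromJSON(path)
    d <- unlist(cfg$divergence_my)
    d <- setNames(as.numeric(d), names(d))
    ref <- cfg$reference_species
    if (is.null(ref)) {
      ref <- names(d)[d == 0]
      if (length(ref) != 1L) stop("reference species (divergence 0) not unique")
    }
    tree <- if (!is.null(cfg$clade_tree)) cfg$clade_tree else ""
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("species", "divergence_my") %in% names(tab)))
      stop("TSV must have columns 'species' and 'divergence_my'")
    if (anyDuplicated(tab$species)) stop("duplicate species in phylogeny table")
    d <- setNames(as.numeric(tab$divergence_my), tab$species)
    ref <- tab$species[tab$divergence_my == 0]
    if (length(ref) != 1L) stop("reference species (divergence 0) missing or not unique")
    tree <- ""
  }
  if (anyDuplicated(names(d))) stop("duplicate species in phylogeny config")
  if (any(d < 0)) stop("negative divergence time")
  if (!(ref %in% names(d)) || d[[ref]] != 0)
    stop("reference species must be present with divergence 0")
  PhylogenyConfig(ref, d, tree)
}

#' Write / read a presence matrix as TSV
#'
#' Genes as rows, species as columns, cells from the call vocabulary; the
#' caller label is stored on a `# caller=` header line.  `readPresenceMatrix`
#' errors on ragged rows and on unknown call tokens, and the write/read
#' round trip is the identity on calls and caller.
#'
#' @param matrix a [PresenceMatrix-class].
#' @param path output/input TSV path.
#' @return `writePresenceMatrix` returns `path` invisibly;
#'   `readPresenceMatrix` returns a [PresenceMatrix-class].
#' @export
writePresenceMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "PresenceMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# caller=", caller(matrix)), con)
  m <- calls(matrix)
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname writePresenceMatrix
#' @export
readPresenceMatrix <- function(path) {
  lines <- readLines(path)
  callerLabel <- "unknown"
  hdr <- grep("^# *caller=", lines, value = TRUE)
  if (length(hdr)) callerLabel <- sub("^# *caller=", "", hdr[1])
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("presence matrix file has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) stop("ragged rows in presence matrix file")
  header <- fields[[1]]
  body <- fields[-1]
  m <- do.call(rbind, lapply(body, function(f) f[-1]))
  rownames(m) <- vapply(body, `[[`, character(1), 1L)
  colnames(m) <- header[-1]
  .checkCallVocab(m)
  PresenceMatrix(m, callerLabel)
}
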