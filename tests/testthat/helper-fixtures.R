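# Small fixture builders; everything is generated in code at test time.

writeToyGenomeFiles <- function(dir = tempfile("toygenome")) {
  dir.create(dir)
  # ctg1: two + strand genes; ctg2: one - strand gene with CDS 1..9 of 12 nt
  ctg1 <- paste0("AAAA", "ATGAAAGGGTAA", "TTTT", "ATGCCC", "CCCC")
  #               1-4     5-16            17-20  21-26     27-30
  ctg2 <- "TTACATGGTCAA"  # revcomp(1..9) = CCATGTAA? computed in tests
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">ctg1", ctg1, ">ctg2", ctg2), fa)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "ctg1\ttoy\tgene\t5\t16\t.\t+\t.\tID=geneA",
    "ctg1\ttoy\tmRNA\t5\t16\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "ctg1\ttoy\tCDS\t5\t16\t.\t+\t0\tID=geneA.c1;Parent=geneA.t1",
    "ctg1\ttoy\tgene\t21\t26\t.\t+\t.\tID=geneB",
    "ctg1\ttoy\tmRNA\t21\t26\t.\t+\t.\tID=geneB.t1;Parent=geneB",
    "ctg1\ttoy\tCDS\t21\t26\t.\t+\t0\tID=geneB.c1;Parent=geneB.t1",
    "ctg2\ttoy\tgene\t1\t9\t.\t-\t.\tID=geneC",
    "ctg2\ttoy\tmRNA\t1\t9\t.\t-\t.\tID=geneC.t1;Parent=geneC",
    "ctg2\ttoy\tCDS\t1\t9\t.\t-\t0\tID=geneC.c1;Parent=geneC.t1"), gff)
  list(dir = dir, fasta = fa, gff3 = gff, ctg1 = ctg1, ctg2 = ctg2)
}

# a clade fixture shared by several pipeline tests (built once per run)
smallCladeFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ref <- forgeReference(nGenes = 20, nContigs = 2, seed = 101)
    phylo <- PhylogenyConfig("reference",
                             c(reference = 0, near = 10, far = 45))
    events <- data.frame(
      gene_id    = c("g004", "g013", "g007", "g016"),
      species_id = c("near", "near", "far", "far"),
      event      = c("lost", "split_across_contigs", "at_contig_end",
                     "diverged_extreme"),
      stringsAsFactors = FALSE)
    forged <- forgeClade(ref, phylo, events = events, seed = 101)
    res <- suppressMessages(
      runOrthologPipeline(geneIds(ref), ref, forged$genomes))
    cache <<- list(ref = ref, phylo = phylo, events = events,
                   forged = forged, res = res)
    cache
  }
})

# manually duplicate one gene inside a genome (appended to its contig end)
withDuplicatedGene <- function(genome, geneId, newId = paste0(geneId, "_dup")) {
  gr <- genes(genome)
  i <- match(geneId, S4Vectors::mcols(gr)$gene_id)
  ctg <- as.character(GenomicRanges::seqnames(gr))[i]
  seqs <- as.character(contigs(genome))
  cds <- S4Vectors::mcols(gr)$cds[i]
  st <- nchar(seqs[[ctg]]) + 1L
  seqs[[ctg]] <- paste0(seqs[[ctg]], cds)
  mc <- S4Vectors::mcols(gr)
  gr2 <- GenomicRanges::GRanges(   # rebuilt without inherited seqinfo
    c(as.character(GenomicRanges::seqnames(gr)), ctg),
    IRanges::IRanges(c(GenomicRanges::start(gr), st),
                     c(GenomicRanges::end(gr), st + nchar(cds) - 1L)),
    strand = c(as.character(GenomicRanges::strand(gr)), "+"))
  S4Vectors::mcols(gr2)$gene_id <- c(mc$gene_id, newId)
  S4Vectors::mcols(gr2)$cds <- c(mc$cds, cds)
  S4Vectors::mcols(gr2)$protein <- c(mc$protein, mc$protein[i])
  S4Vectors::mcols(gr2)$untranslatable <- c(mc$untranslatable, FALSE)
  AnnotatedGenome(speciesId(genome),
                  Biostrings::DNAStringSet(seqs), gr2)
}
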