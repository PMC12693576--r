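Package: OrthoTrace
Title: Ortholog Presence/Absence Calling with Synteny Rescue, Neutrality
    Tests and Shared-Control Estimation Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for calling gene orthologs present
    or absent across a clade of annotated genomes.  Implements a
    reciprocal-best-hit protein search stage, a synteny-aware re-evaluation of
    preliminary absences using up to three flanking anchor genes per side
    (with rescue of genes split across contigs or truncated at contig ends,
    and an in-silico analogue of PCR validation across retained syntenic
    blocks), confidence tiering of absences by phylogenetic support, the
    McDonald-Kreitman test with low-frequency polymorphism exclusion and
    lineage-specific divergence against a supplied ancestral sequence, and
    shared-control estimation statistics (bootstrap BCa effect sizes and
    permutation tests) for fertility assay counts.  A synthetic-data forge
    generates clades of annotated genomes with known ortholog truth, codon
    alignments with planted substitution counts, and overdispersed progeny
    counts, so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ComparativeGenomics, Genetics, Alignment, Software
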