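## Deterministic local-alignment search engine (BLAST stand-in) ---------

#' Scoring schemes for local alignment
#'
#' BLAST-like defaults: BLOSUM62 with affine gap open 11 / extend 1 for
#' protein; match +2 / mismatch -3 with gap open 5 / extend 2 for
#' nucleotide.  A gap of length L costs `gapOpen + L * gapExtend`.  Unknown
#' residues are mapped to `X` (protein) or `N` (nucleotide), which score as
#' mismatch-only symbols.
#'
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param gapOpen,gapExtend affine gap parameters (positive costs).
#' @return a scoring scheme list with elements `matrix`, `gapOpen`,
#'   `gapExtend`, `alphabet`.
#' @examples
#' proteinScoring()$gapOpen
#' nucleotideScoring(match = 1, mismatch = -1)$matrix["A", "A"]
#' @export
proteinScoring <- function(gapOpen = 11, gapExtend = 1) {
  if (is.null(.ot_cache$BLOSUM62)) {
    b62 <- NULL
    data("BLOSUM62", package = "Biostrings", envir = environment())
    .ot_cache$BLOSUM62 <- get("BLOSUM62", envir = environment())
  }
  list(matrix = .ot_cache$BLOSUM62, gapOpen = gapOpen, gapExtend = gapExtend,
       alphabet = "protein")
}

#' @rdname proteinScoring
#' @export
nucleotideScoring <- function(match = 2, mismatch = -3, gapOpen = 5,
                              gapExtend = 2) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch   # N never matches, even itself
  list(matrix = m, gapOpen = gapOpen, gapExtend = gapExtend,
       alphabet = "nucleotide")
}

.cleanSeq <- function(x, scoring) {
  x <- toupper(as.character(x))
  known <- rownames(scoring$matrix)
  chars <- strsplit(x, "", fixed = TRUE)
  sub <- if (scoring$alphabet == "protein") "X" else "N"
  vapply(chars, function(cc) {
    bad <- !(cc %in% known)
    if (any(bad)) {
      warning("unknown residue(s) treated as mismatch-only symbol '", sub, "'")
      cc[bad] <- sub
    }
    paste(cc, collapse = "")
  }, character(1))
}

.xs <- function(x, scoring) {
  if (scoring$alphabet == "protein") AAStringSet(x) else DNAStringSet(x)
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman local alignment under affine gaps (no heuristic
#' seeding), with the score floored at 0: when no alignment scores
#' positively the empty alignment is reported.  Percent identity is
#' computed as identical aligned columns over all aligned columns (gap
#' columns count in the denominator); coverages are the aligned span of
#' each sequence divided by its full length.
#'
#' @param a query sequence (character or XString).
#' @param b subject sequence.
#' @param scoring a scheme from [proteinScoring()] or [nucleotideScoring()].
#' @return a list: `score`, `identity` (fraction), `queryCoverage`,
#'   `subjectCoverage`, `queryRange`, `subjectRange` (integer c(start, end),
#'   `c(0, 0)` for the empty alignment), `alignedQuery`, `alignedSubject`.
#' @examples
#' alignLocal("MKV", "MKV", proteinScoring())$score
#' alignLocal("ACGT", "TTTT", nucleotideScoring(1, -1, 2, 1))$score
#' @export
alignLocal <- function(a, b, scoring = proteinScoring()) {
  a <- .cleanSeq(a, scoring); b <- .cleanSeq(b, scoring)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  hit <- .alignSet(.xs(b, scoring), .xs(a, scoring)[[1]], scoring)
  list(score = hit$score[1], identity = hit$identity[1],
       queryCoverage = hit$query_coverage[1],
       subjectCoverage = hit$subject_coverage[1],
       queryRange = c(hit$qstart[1], hit$qend[1]),
       subjectRange = c(hit$sstart[1], hit$send[1]),
       alignedQuery = hit$aligned_query[1],
       alignedSubject = hit$aligned_subject[1])
}

# all queries x all subjects in one vectorized pairwiseAlignment call
# (elementwise over repeated sets); scores/identities are symmetric, so one
# run serves both search directions with coverages swapped
.alignPairs <- function(queries, subjects, scoring) {
  nq <- length(queries); ns <- length(subjects)
  pat <- rep(subjects, times = nq)
  sub <- rep(queries, each = ns)
  pa <- pairwiseAlignment(pat, sub, type = "local",
                          substitutionMatrix = scoring$matrix,
                          gapOpening = scoring$gapOpen,
                          gapExtension = scoring$gapExtend)
  sc <- score(pa)
  idf <- pid(pa, type = "PID1") / 100
  qs <- start(subject(pa)); qe <- end(subject(pa))
  ss <- start(pattern(pa)); se <- end(pattern(pa))
  empty <- sc <= 0
  sc[empty] <- 0; idf[empty] <- 0
  qs[empty] <- 0L; qe[empty] <- -1L; ss[empty] <- 0L; se[empty] <- -1L
  data.frame(
    query_id = rep(names(queries), each = ns),
    subject_id = rep(names(subjects), times = nq),
    score = sc, identity = idf,
    query_coverage = pmax(0, qe - qs + 1L) / rep(width(queries), each = ns),
    subject_coverage = pmax(0, se - ss + 1L) / rep(width(subjects), times = nq),
    qstart = qs, qend = qe, sstart = ss, send = se,
    stringsAsFactors = FALSE)
}

.sortHits <- function(hits) {
  hits <- hits[order(-hits$score, -hits$identity, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# vectorized core: one query (XString) against a set of subjects.
# pairwiseAlignment treats its 'pattern' as the vectorized side, so subjects
# go in as patterns and the query as subject; scores are symmetric.
.alignSet <- function(subjects, query, scoring) {
  pa <- pairwiseAlignment(subjects, query, type = "local",
                          substitutionMatrix = scoring$matrix,
                          gapOpening = scoring$gapOpen,
                          gapExtension = scoring$gapExtend)
  sc <- score(pa)
  alS <- as.character(alignedPattern(pa))   # aligned subject strings
  alQ <- as.character(alignedSubject(pa))   # aligned query strings
  idf <- pid(pa, type = "PID1") / 100       # identical / aligned columns
  qlen <- length(query)
  slen <- width(subjects)
  qs <- start(subject(pa)); qe <- end(subject(pa))
  ss <- start(pattern(pa)); se <- end(pattern(pa))
  empty <- sc <= 0
  sc[empty] <- 0; idf[empty] <- 0
  qs[empty] <- 0L; qe[empty] <- -1L; ss[empty] <- 0L; se[empty] <- -1L
  alQ[empty] <- ""; alS[empty] <- ""
  data.frame(
    subject_id = if (is.null(names(subjects))) as.character(seq_along(subjects))
                 else names(subjects),
    score = sc, identity = idf,
    query_coverage = pmax(0, qe - qs + 1L) / qlen,
    subject_coverage = pmax(0, se - ss + 1L) / slen,
    qstart = qs, qend = qe, sstart = ss, send = se,
    aligned_query = alQ, aligned_subject = alS,
    stringsAsFactors = FALSE)
}

#' Search a query against a sequence database
#'
#' Aligns the query locally against every database entry, drops hits below
#' `minScore`, and returns the hit table sorted by descending score, ties
#' broken by higher identity then lexicographic subject id.
#'
#' @param query sequence (character or XString).
#' @param database named character vector or XStringSet.
#' @param scoring scoring scheme.
#' @param minScore hits with score below this are dropped.
#' @return a `data.frame` hit table (columns `subject_id`, `score`,
#'   `identity`, `query_coverage`, `subject_coverage`, `qstart`, `qend`,
#'   `sstart`, `send`).
#' @examples
#' db <- c(g1 = "MKVLLAG", g2 = "MKVWLAG", g3 = "PPPPPPP")
#' searchHits("MKVLLAG", db, proteinScoring(), minScore = 10)
#' @export
searchHits <- function(query, database, scoring = proteinScoring(),
                       minScore = 0) {
  if (length(database) == 0L) stop("database is empty")
  dbChr <- .cleanSeq(as.character(database), scoring)
  names(dbChr) <- names(database)
  q <- .cleanSeq(query, scoring)
  if (nchar(q) == 0L) stop("empty sequence")
  hits <- .alignSet(.xs(dbChr, scoring), .xs(q, scoring)[[1]], scoring)
  hits <- hits[hits$score >= minScore, , drop = FALSE]
  hits <- hits[order(-hits$score, -hits$identity, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("subject_id", "score", "identity", "query_coverage",
           "subject_coverage", "qstart", "qend", "sstart", "send")]
}

#' Import a BLAST tabular (outfmt 6) file as a hit table
#'
#' Adapter for an external search engine: reads the standard 12-column
#' BLAST `-outfmt 6` layout (optionally extended with `qlen`/`slen` as
#' columns 13-14, from which coverages are computed) into the same hit
#' table dialect produced by [searchHits()], with the bit score as `score`.
#'
#' @param path path to the tabular file.
#' @return a `data.frame` with one row per hit, sorted per query by the
#'   [searchHits()] ordering.
#' @export
readBlastTab <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected >= 12 columns of BLAST outfmt 6")
  names(tab)[1:12] <- cols
  qcov <- scov <- rep(NA_real_, nrow(tab))
  if (ncol(tab) >= 14L) {
    qcov <- abs(tab$qend - tab$qstart + 1) / tab[[13]]
    scov <- abs(tab$send - tab$sstart + 1) / tab[[14]]
  }
  out <- data.frame(query_id = tab$query_id, subject_id = tab$subject_id,
                    score = tab$bitscore, identity = tab$pident / 100,
                    query_coverage = qcov, subject_coverage = scov,
                    qstart = tab$qstart, qend = tab$qend,
                    sstart = tab$sstart, send = tab$send,
                    stringsAsFactors = FALSE)
  out[order(out$query_id, -out$score, -out$identity, out$subject_id), ,
      drop = FALSE]
}
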