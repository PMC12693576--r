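## McDonald-Kreitman test with frequency filtering ----------------------

# pathway-averaged synonymous/nonsynonymous step counts between two codons
# (Nei-Gojobori style): all orderings of the differing positions, equal
# weights, paths through stop codons excluded; NA when no valid path
.ngPair <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dif <- which(a != b)
  perms <- switch(as.character(length(dif)),
    "1" = list(dif),
    "2" = list(dif, dif[2:1]),
    "3" = list(dif[c(1, 2, 3)], dif[c(1, 3, 2)], dif[c(2, 1, 3)],
               dif[c(2, 3, 1)], dif[c(3, 1, 2)], dif[c(3, 2, 1)]))
  acc <- c(0, 0); nValid <- 0L
  for (ord in perms) {
    cur <- a; syn <- 0; nonsyn <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      curC <- paste(cur, collapse = ""); nxtC <- paste(nxt, collapse = "")
      if (GENETIC_CODE[[nxtC]] == "*" && nxtC != c2) { ok <- FALSE; break }
      if (GENETIC_CODE[[curC]] == GENETIC_CODE[[nxtC]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(syn, nonsyn); nValid <- nValid + 1L }
  }
  if (nValid == 0L) return(c(syn = NA_real_, nonsyn = NA_real_))
  setNames(acc / nValid, c("syn", "nonsyn"))
}

# 64x64 lookup, built once
.ngTables <- function() {
  if (!is.null(.ot_cache$ngSyn)) return(list(syn = .ot_cache$ngSyn,
                                             nonsyn = .ot_cache$ngNonsyn))
  n <- length(.CODONS)
  synM <- matrix(NA_real_, n, n, dimnames = list(.CODONS, .CODONS))
  nonsynM <- synM
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (GENETIC_CODE[[.CODONS[i]]] == "*" || GENETIC_CODE[[.CODONS[j]]] == "*")
      next
    v <- .ngPair(.CODONS[i], .CODONS[j])
    synM[i, j] <- v["syn"]; nonsynM[i, j] <- v["nonsyn"]
  }
  .ot_cache$ngSyn <- synM; .ot_cache$ngNonsyn <- nonsynM
  list(syn = synM, nonsyn = nonsynM)
}

.codonMatrix <- function(seqs) {
  chr <- as.character(seqs)
  L <- nchar(chr[1]) %/% 3L
  m <- matrix("", length(chr), L)
  starts <- seq(1, by = 3, length.out = L)
  for (i in seq_along(chr)) m[i, ] <- substring(chr[i], starts, starts + 2L)
  m
}

#' Tabulate per-codon fixed and polymorphic changes
#'
#' Scans each codon column of a [CodonAlignment-class].  A column with two
#' or more ingroup alleles contributes polymorphic changes: each minor
#' allele is compared to the major allele and its mutational steps are
#' classified synonymous/nonsynonymous by codon-table comparison,
#' multi-step differences averaged with equal weight over all shortest
#' mutational pathways that avoid stop codons (fractional contributions);
#' the minor-allele frequency is recorded.  A column where the ingroup is
#' monomorphic but differs from the ancestor contributes a fixed change
#' (lineage-specific by construction, since the ancestor predates the
#' split from the sister lineage).  Columns containing gaps or ambiguity
#' in any used sequence, ingroup stop codons, or codon pairs with no valid
#' mutational pathway are excluded and counted.
#'
#' @param aln a [CodonAlignment-class].
#' @return a data.frame with one row per mutational change: `codon`
#'   (1-based column), `kind` (`fixed`/`polymorphic`), `syn`, `nonsyn`
#'   (fractional step counts), `maf` (minor-allele frequency, `NA` for
#'   fixed).  Attribute `excluded` carries the excluded-column count.
#' @examples
#' aln <- CodonAlignment(Biostrings::DNAStringSet(c(a = "AAA", b = "AAA")),
#'                       Biostrings::DNAStringSet(c(anc = "AAG")))
#' tabulateChanges(aln)   # one fixed synonymous change (Lys -> Lys)
#' @export
tabulateChanges <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  ng <- .ngTables()
  ing <- .codonMatrix(aln@ingroup)
  anc <- .codonMatrix(aln@ancestor)[1, ]
  n <- nrow(ing); L <- length(anc)
  valid <- .CODONS                      # gap/ambiguity codons fall outside
  stopCodons <- .CODONS[GENETIC_CODE == "*"]

  # column classes, vectorized: monomorphic-and-ancestral columns skipped
  mono <- colSums(ing != matrix(ing[1, ], n, L, byrow = TRUE)) == 0L
  fixedCols <- which(mono & ing[1, ] != anc)
  polyCols <- which(!mono)

  # accumulators (grown by index, not by data.frame rbind)
  cap <- length(fixedCols) + length(polyCols) * 2L + 8L
  codonV <- integer(cap); kindV <- character(cap)
  synV <- numeric(cap); nonsynV <- numeric(cap); mafV <- numeric(cap)
  nOut <- 0L; excluded <- 0L
  push <- function(j, kind, s, nsy, maf) {
    nOut <<- nOut + 1L
    if (nOut > length(codonV)) {        # grow
      codonV <<- c(codonV, integer(cap)); kindV <<- c(kindV, character(cap))
      synV <<- c(synV, numeric(cap)); nonsynV <<- c(nonsynV, numeric(cap))
      mafV <<- c(mafV, numeric(cap))
    }
    codonV[nOut] <<- j; kindV[nOut] <<- kind
    synV[nOut] <<- s; nonsynV[nOut] <<- nsy; mafV[nOut] <<- maf
  }

  for (j in fixedCols) {
    allele <- ing[1, j]
    if (!(allele %in% valid) || !(anc[j] %in% valid)) {
      excluded <- excluded + 1L; next
    }
    if (allele %in% stopCodons) {
      warning("ingroup stop codon at codon ", j, "; column excluded")
      excluded <- excluded + 1L; next
    }
    s <- ng$syn[anc[j], allele]
    if (is.na(s)) { excluded <- excluded + 1L; next }
    push(j, "fixed", s, ng$nonsyn[anc[j], allele], NA_real_)
  }
  for (j in polyCols) {
    alleles <- ing[, j]
    if (!all(c(alleles, anc[j]) %in% valid)) { excluded <- excluded + 1L; next }
    if (any(alleles %in% stopCodons)) {
      warning("ingroup stop codon at codon ", j, "; column excluded")
      excluded <- excluded + 1L; next
    }
    tab <- table(alleles)
    major <- names(tab)[order(-tab, names(tab))][1]
    minors <- setdiff(names(tab), major)
    s <- ng$syn[major, minors]; nsy <- ng$nonsyn[major, minors]
    if (anyNA(s)) { excluded <- excluded + 1L; next }
    for (k in seq_along(minors))
      push(j, "polymorphic", s[k], nsy[k], as.numeric(tab[[minors[k]]]) / n)
  }
  keep <- seq_len(nOut)
  out <- data.frame(codon = codonV[keep], kind = kindV[keep],
                    syn = synV[keep], nonsyn = nonsynV[keep],
                    maf = mafV[keep], stringsAsFactors = FALSE)
  out <- out[order(out$codon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "nIngroup") <- n
  out
}

#' Exclude low-frequency polymorphisms
#'
#' Removes polymorphic changes whose minor-allele frequency is strictly
#' below `cutoff` (slightly deleterious alleles not yet removed by
#' purifying selection); a change at exactly the cutoff is retained.
#' Fixed changes are untouched.
#'
#' @param changes a change table from [tabulateChanges()].
#' @param cutoff frequency cutoff in `[0, 0.5]` (default 0.12).
#' @return the filtered change table; attribute `nFiltered` counts the
#'   removed polymorphic changes, `freqCutoff` records the cutoff.
#' @export
applyFrequencyFilter <- function(changes, cutoff = 0.12) {
  stopifnot(cutoff >= 0, cutoff <= 0.5)
  drop <- changes$kind == "polymorphic" & changes$maf < cutoff
  out <- changes[!drop, , drop = FALSE]
  attr(out, "excluded") <- attr(changes, "excluded")
  attr(out, "nIngroup") <- attr(changes, "nIngroup")
  attr(out, "nFiltered") <- sum(drop)
  attr(out, "freqCutoff") <- cutoff
  out
}

#' Build the McDonald-Kreitman 2x2 table
#'
#' Sums the (fractional) synonymous/nonsynonymous steps of fixed and
#' polymorphic changes into Dn, Ds, Pn, Ps; applies the two-tailed Fisher
#' exact test to the nearest-integer-rounded table; computes
#' NI = (Pn/Ps)/(Dn/Ds) and alpha = 1 - NI (reported `NA` when a
#' denominator is zero).  An all-zero table yields p = 1 by convention.
#'
#' @param changes a change table from [tabulateChanges()] (optionally
#'   filtered by [applyFrequencyFilter()]).
#' @return an [MKTResult-class].
#' @examples
#' sim <- simulateCodonSet(60, 10,
#'   planted = list(fixedNonsyn = 5, fixedSyn = 10,
#'                  polyNonsyn = rep(0.5, 4), polySyn = rep(0.5, 8)),
#'   seed = 1)
#' buildMKT(tabulateChanges(sim$alignment))
#' @export
buildMKT <- function(changes) {
  fx <- changes$kind == "fixed"
  counts <- c(Dn = sum(changes$nonsyn[fx]), Ds = sum(changes$syn[fx]),
              Pn = sum(changes$nonsyn[!fx]), Ps = sum(changes$syn[!fx]))
  rounded <- as.integer(round(counts))
  names(rounded) <- names(counts)
  p <- fisherTwoTailed(matrix(rounded, 2, 2, byrow = TRUE))
  ni <- if (counts["Dn"] > 0 && counts["Ds"] > 0 && counts["Ps"] > 0)
    unname((counts["Pn"] / counts["Ps"]) / (counts["Dn"] / counts["Ds"]))
  else NA_real_
  new("MKTResult", counts = counts, countsRounded = rounded,
      freqCutoff = attr(changes, "freqCutoff") %||% 0,
      pValue = p, ni = ni, alpha = if (is.na(ni)) NA_real_ else 1 - ni,
      nExcludedCodons = as.integer(attr(changes, "excluded") %||% 0L),
      nFilteredPoly = as.integer(attr(changes, "nFiltered") %||% 0L))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact p-value by summing hypergeometric point probabilities, over all
#' tables with the observed margins, of every table whose point
#' probability does not exceed the observed one (within a small relative
#' slack for floating-point ties).  An all-zero table returns 1.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return the two-tailed p-value.
#' @examples
#' fisherTwoTailed(matrix(c(1, 1, 1, 1), 2))         # 1
#' fisherTwoTailed(matrix(c(0, 5, 5, 0), 2))         # 2/252
#' @export
fisherTwoTailed <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("negative entry in contingency table")
  if (any(abs(tab - round(tab)) > 1e-9)) stop("table entries must be integers")
  tab <- round(tab)
  if (sum(tab) == 0) return(1)
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  pObs <- dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Run the McDonald-Kreitman test on a codon alignment
#'
#' [tabulateChanges()], [applyFrequencyFilter()] and [buildMKT()] in one
#' call.
#'
#' @param aln a [CodonAlignment-class].
#' @param cutoff minor-allele-frequency cutoff (default 0.12; strict `<`).
#' @return an [MKTResult-class].
#' @export
mktTest <- function(aln, cutoff = 0.12) {
  buildMKT(applyFrequencyFilter(tabulateChanges(aln), cutoff))
}

#' Parsimony fallback for the ancestral sequence
#'
#' When no reconstructed common-ancestor sequence is available, infers one
#' site-by-site by majority-rule consensus of the ingroup followed by
#' unweighted parsimony among (consensus, sister, outgroup): the ancestor
#' takes the value shared by at least two of the three; irreconcilable
#' sites (all three distinct) are masked with `N` (excluded downstream)
#' and counted.
#'
#' @param ingroup [Biostrings::DNAStringSet] of aligned ingroup sequences.
#' @param sister aligned sister-lineage sequence (character or XString).
#' @param outgroup aligned outgroup sequence.
#' @return a list: `ancestor` (character), `nUnresolved`.
#' @export
inferAncestorParsimony <- function(ingroup, sister, outgroup) {
  ingM <- do.call(rbind, strsplit(as.character(ingroup), ""))
  sis <- strsplit(as.character(sister), "")[[1]]
  out <- strsplit(as.character(outgroup), "")[[1]]
  stopifnot(ncol(ingM) == length(sis), length(sis) == length(out))
  cons <- apply(ingM, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) "N" else names(tb)[1]
  })
  anc <- character(length(cons))
  for (i in seq_along(cons)) {
    v <- c(cons[i], sis[i], out[i])
    anc[i] <- if (cons[i] == sis[i]) cons[i]
      else if (sis[i] == out[i]) sis[i]
      else if (cons[i] == out[i]) cons[i]
      else "N"
  }
  list(ancestor = paste(anc, collapse = ""), nUnresolved = sum(anc == "N"))
}

#' Read a role-tagged codon alignment from FASTA
#'
#' Sequence roles are taken from the FASTA headers: a header containing
#' `ancestor` or `outgroup` (word or `role=` tag) is assigned that role;
#' everything else is ingroup.
#'
#' @param path FASTA of equal-length, in-frame aligned sequences.
#' @return a [CodonAlignment-class].
#' @export
readCodonAlignment <- function(path) {
  seqs <- readDNAStringSet(path)
  nm <- tolower(names(seqs))
  isAnc <- grepl("(^|[^a-z])ancestor([^a-z]|$)|role=ancestor", nm)
  isOut <- grepl("(^|[^a-z])outgroup([^a-z]|$)|role=outgroup", nm)
  CodonAlignment(seqs[!isAnc & !isOut], seqs[isAnc], seqs[isOut])
}
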