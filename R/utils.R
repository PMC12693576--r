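## Call vocabulary ------------------------------------------------------

.CALL_LEVELS <- c(
  "PRESENT_REFERENCE", "PRESENT_RBBH", "PRESENT_RESCUED", "PRESENT",
  "ABSENT_PRELIM", "ABSENT_SYNTENY", "ABSENT_NO_SYNTENY", "ABSENT",
  "UNRESOLVED_CONTIG_END"
)

#' Is a call token a presence / an absence?
#'
#' Helpers over the presence/absence call vocabulary used throughout the
#' package (`PRESENT_REFERENCE`, `PRESENT_RBBH`, `PRESENT_RESCUED`,
#' `PRESENT`, `ABSENT_PRELIM`, `ABSENT_SYNTENY`, `ABSENT_NO_SYNTENY`,
#' `ABSENT`, `UNRESOLVED_CONTIG_END`).  `UNRESOLVED_CONTIG_END` is neither
#' present nor absent.
#'
#' @param x character vector of call tokens.
#' @return logical vector.
#' @examples
#' isPresentCall(c("PRESENT_RBBH", "ABSENT_SYNTENY"))
#' isAbsentCall("UNRESOLVED_CONTIG_END")
#' @export
isPresentCall <- function(x) {
  r <- startsWith(x, "PRESENT")
  if (is.matrix(x)) { dim(r) <- dim(x); dimnames(r) <- dimnames(x) }
  r
}

#' @rdname isPresentCall
#' @export
isAbsentCall <- function(x) {
  r <- startsWith(x, "ABSENT")
  if (is.matrix(x)) { dim(r) <- dim(x); dimnames(r) <- dimnames(x) }
  r
}

.checkCallVocab <- function(x) {
  bad <- setdiff(unique(as.vector(x)), .CALL_LEVELS)
  if (length(bad))
    stop("unknown call token(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

## misc -----------------------------------------------------------------

.stageMsg <- function(...) message("[OrthoTrace] ", sprintf(...))

# stable seed derivation below 2^31 for independent sub-streams
.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483647L)
}
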