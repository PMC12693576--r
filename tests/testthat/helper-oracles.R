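# Independent oracles, deliberately simple and separate from the package
# implementations they check.

# plain-R Gotoh local alignment (affine gaps, score floored at 0);
# gap of length L costs open + L * ext
swOracle <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in the first sequence
  F <- matrix(-Inf, n + 1, m + 1)  # gap in the second sequence
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# exhaustive two-tailed Fisher p over all tables with the observed margins,
# probabilities from log-binomial coefficients
fisherOracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m + n2 == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  lp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  probs <- exp(lp)
  pObs <- probs[support == a]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# exact permutation p for |mean difference| by full enumeration of label
# assignments (small total n only)
permOracle <- function(control, group) {
  pooled <- c(control, group)
  nC <- length(control)
  obs <- abs(mean(group) - mean(control))
  splits <- utils::combn(length(pooled), nC)
  stats <- apply(splits, 2, function(idx)
    abs(mean(pooled[-idx]) - mean(pooled[idx])))
  mean(stats >= obs - 1e-12)
}

# independent re-implementation of the documented bootstrap protocol
# (control index matrix first, then group, single sample.int calls)
bootOracleDeltas <- function(control, group, nBoot, seed) {
  set.seed(seed)
  nC <- length(control); nG <- length(group)
  idxC <- matrix(sample.int(nC, nC * nBoot, replace = TRUE), nrow = nBoot)
  idxG <- matrix(sample.int(nG, nG * nBoot, replace = TRUE), nrow = nBoot)
  vapply(seq_len(nBoot), function(b)
    mean(group[idxG[b, ]]) - mean(control[idxC[b, ]]), numeric(1))
}

# brute-force percent-identity / coverage check helper: align two short
# sequences by hand is unnecessary; tests use exact constructions instead
randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
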