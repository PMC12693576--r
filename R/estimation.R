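## Shared-control estimation statistics ---------------------------------

#' Mean-difference effect size
#'
#' `mean(group) - mean(control)`, in progeny units.
#'
#' @param control,group numeric count vectors (n >= 2 each for inference;
#'   non-empty here).
#' @return the mean difference.
#' @examples
#' meanDifference(c(10, 20, 30), c(0, 0, 0))   # -20
#' @export
meanDifference <- function(control, group) {
  if (!length(control) || !length(group)) stop("empty group")
  mean(group) - mean(control)
}

# resampling protocol (documented so an independent implementation can
# reproduce it exactly): set.seed(seed); draw the control index matrix
# (nBoot x nC) with one sample.int call, then the group index matrix
# (nBoot x nG); per-replicate delta = rowMeans(group draws) - rowMeans(
# control draws)
.bootDeltas <- function(control, group, nBoot, seed) {
  set.seed(seed)
  nC <- length(control); nG <- length(group)
  idxC <- matrix(sample.int(nC, nC * nBoot, replace = TRUE), nrow = nBoot)
  idxG <- matrix(sample.int(nG, nG * nBoot, replace = TRUE), nrow = nBoot)
  rowMeans(matrix(group[idxG], nrow = nBoot)) -
    rowMeans(matrix(control[idxC], nrow = nBoot))
}

#' Bootstrap confidence interval for a shared-control mean difference
#'
#' Resamples each group independently with replacement `nBoot` times and
#' returns a bias-corrected-and-accelerated (BCa) interval for the mean
#' difference: bias correction z0 from the fraction of resampled deltas
#' below the observed delta, acceleration from the jackknife over all
#' observations of both groups.  Falls back to the percentile interval
#' with a warning when z0 is degenerate (every resample on one side).
#' All-constant groups yield a zero-width interval at the observed delta,
#' with a warning.
#'
#' @param control,group numeric count vectors (n >= 2 each).
#' @param nBoot bootstrap replicates (default 5000).
#' @param level confidence level (default 0.95).
#' @param method `"bca"` (default) or `"percentile"`.
#' @param seed RNG seed (required for reproducibility).
#' @return a list: `ciLow`, `ciHigh`, `delta`, `nBoot`, `method`
#'   (method actually used), `seed`.
#' @examples
#' set.seed(1)
#' bootstrapCI(rnbinom(20, mu = 50, size = 5), rep(0, 20),
#'             nBoot = 500, seed = 42)[c("ciLow", "ciHigh")]
#' @export
bootstrapCI <- function(control, group, nBoot = 5000, level = 0.95,
                        method = c("bca", "percentile"), seed) {
  method <- match.arg(method)
  if (length(control) < 2 || length(group) < 2) stop("need n >= 2 per group")
  if (missing(seed)) stop("seed is required")
  obs <- meanDifference(control, group)
  if (sd(control) == 0 && sd(group) == 0) {
    warning("both groups constant; zero-width interval at the observed delta")
    return(list(ciLow = obs, ciHigh = obs, delta = obs, nBoot = nBoot,
                method = "degenerate", seed = seed))
  }
  deltas <- .bootDeltas(control, group, nBoot, seed)
  alpha <- (1 - level) / 2
  usedMethod <- method
  if (method == "bca") {
    propBelow <- mean(deltas < obs)
    if (propBelow == 0 || propBelow == 1) {
      warning("degenerate bias correction; falling back to percentile interval")
      usedMethod <- "percentile"
    } else {
      z0 <- qnorm(propBelow)
      # jackknife over the pooled observations (delete-one, either group)
      nC <- length(control); nG <- length(group)
      jack <- c(
        vapply(seq_len(nC), function(i) mean(group) - mean(control[-i]),
               numeric(1)),
        vapply(seq_len(nG), function(i) mean(group[-i]) - mean(control),
               numeric(1)))
      jm <- mean(jack)
      denom <- sum((jm - jack)^2)^1.5
      a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
      adj <- function(zq) pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
      lo <- adj(qnorm(alpha)); hi <- adj(qnorm(1 - alpha))
      ci <- unname(quantile(deltas, c(lo, hi), type = 7))
      return(list(ciLow = ci[1], ciHigh = ci[2], delta = obs, nBoot = nBoot,
                  method = "bca", seed = seed))
    }
  }
  ci <- unname(quantile(deltas, c(alpha, 1 - alpha), type = 7))
  list(ciLow = ci[1], ciHigh = ci[2], delta = obs, nBoot = nBoot,
       method = usedMethod, seed = seed)
}

#' Permutation p-value for a two-group mean difference
#'
#' Test statistic |mean difference|; group labels are reshuffled `nPerm`
#' times and the p-value computed with the add-one rule
#' `p = (1 + #permutations >= observed) / (nPerm + 1)`, so `p >=
#' 1/(nPerm+1)` always.  When no permutation reaches the observed
#' statistic the result is flagged as the reporting bound
#' `< 1/(nPerm+1)`.
#'
#' @param control,group numeric count vectors (n >= 2 each).
#' @param nPerm number of permutations (default 10000; < 100 warns).
#' @param seed RNG seed.
#' @return a list: `p`, `isBound` (`TRUE` when p is the `< 1/(nPerm+1)`
#'   bound), `observed`, `nPerm`, `seed`.
#' @examples
#' permutationP(c(1, 2, 3), c(10, 11, 12), nPerm = 1000, seed = 1)$p
#' @export
permutationP <- function(control, group, nPerm = 10000, seed) {
  if (length(control) < 2 || length(group) < 2) stop("need n >= 2 per group")
  if (missing(seed)) stop("seed is required")
  if (nPerm < 100) warning("fewer than 100 permutations; p is very coarse")
  obs <- abs(meanDifference(control, group))
  pooled <- c(control, group)
  nC <- length(control); nTot <- length(pooled)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(nTot, nC)
    stat <- abs(mean(pooled[-idx]) - mean(pooled[idx]))
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  p <- (1 + hits) / (nPerm + 1)
  list(p = p, isBound = hits == 0L, observed = obs, nPerm = nPerm,
       seed = seed)
}

#' Shared-control effect sizes for a fertility dataset
#'
#' Compares every non-control genotype to the single shared control:
#' mean-difference effect size, BCa bootstrap confidence interval and
#' permutation p-value per comparison; significance is declared when the
#' null effect (0) lies outside the confidence interval.  No multiplicity
#' correction is applied across comparisons.
#'
#' @param data a data.frame with columns `genotype` and `progeny`
#'   (e.g. from [simulateFertility()]).
#' @param control the shared control genotype label (default
#'   `"wildtype"`).
#' @param nBoot,nPerm,level see [bootstrapCI()] / [permutationP()].
#' @param seed RNG seed; per-comparison seeds are derived from it.
#' @return a data.frame, one row per comparison: `comparison`, `n`,
#'   `delta`, `ciLow`, `ciHigh`, `pPerm`, `pIsBound`, `significant`.
#' @examples
#' fd <- simulateFertility(list(wildtype = list(mean = 50, dispersion = 5),
#'                              null = "sterile"), n = 15, seed = 3)
#' effectSizes(fd, nBoot = 500, nPerm = 500, seed = 3)
#' @export
effectSizes <- function(data, control = "wildtype", nBoot = 5000,
                        nPerm = 10000, level = 0.95, seed = 1) {
  stopifnot(all(c("genotype", "progeny") %in% names(data)))
  if (!(control %in% data$genotype))
    stop("control genotype '", control, "' not in data")
  ctrl <- data$progeny[data$genotype == control]
  others <- setdiff(unique(data$genotype), control)
  rows <- list()
  for (i in seq_along(others)) {
    g <- others[i]
    grp <- data$progeny[data$genotype == g]
    ci <- bootstrapCI(ctrl, grp, nBoot = nBoot, level = level,
                      seed = .deriveSeed(seed, i))
    pt <- permutationP(ctrl, grp, nPerm = nPerm,
                       seed = .deriveSeed(seed, 1000 + i))
    rows[[i]] <- data.frame(
      comparison = paste0(g, " vs ", control), n = length(grp),
      delta = ci$delta, ciLow = ci$ciLow, ciHigh = ci$ciHigh,
      pPerm = pt$p, pIsBound = pt$isBound,
      significant = ci$ciLow > 0 | ci$ciHigh < 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
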