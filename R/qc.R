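## Genotype-level quality control: call rate, minor allele frequency,
## Hardy-Weinberg exact test, and sliding-window LD pruning.

#' QC threshold set
#'
#' Defaults: MAF >= 0.05, call rate >= 0.7, HWE exact p >= 5e-6 (variants
#' strictly below any threshold are removed), and LD pruning in sliding
#' windows of 100 variants stepping by 10, removing one of each pair with
#' r-squared above 0.5.
#'
#' @param mafMin minimum minor allele frequency.
#' @param callRateMin minimum genotype call rate.
#' @param hwePMin minimum Hardy-Weinberg exact-test p-value.
#' @param ldWindow LD pruning window size (variants).
#' @param ldStep LD pruning step (variants); must be <= `ldWindow`.
#' @param ldR2Max maximum tolerated squared correlation within a window.
#' @return a validated list of class `QcThresholds`.
#' @export
qcThresholds <- function(mafMin = 0.05, callRateMin = 0.7, hwePMin = 5e-6,
                         ldWindow = 100L, ldStep = 10L, ldR2Max = 0.5) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, callRateMin >= 0, callRateMin <= 1,
            hwePMin >= 0, hwePMin <= 1, ldWindow >= 1, ldStep >= 1,
            ldStep <= ldWindow, ldR2Max >= 0, ldR2Max <= 1)
  structure(list(mafMin = mafMin, callRateMin = callRateMin,
                 hwePMin = hwePMin, ldWindow = as.integer(ldWindow),
                 ldStep = as.integer(ldStep), ldR2Max = ldR2Max),
            class = "QcThresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, enumerate all
#' compatible heterozygote counts, and sum the probabilities of all
#' configurations no more probable than the observed one (standard exact
#' test, not mid-p). Monomorphic sites have a single configuration and
#' return p = 1.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts at one site (vectors allowed;
#'   recycled jointly).
#' @return exact p-value(s) in (0, 1].
#' @examples
#' hweExactTest(5, 0, 0)   # 1
#' hweExactTest(0, 2, 0)
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  n <- cbind(nHomRef, nHet, nHomAlt)
  if (any(n < 0)) stop("genotype counts must be non-negative")
  if (any(rowSums(n) == 0)) stop("at least one genotyped sample required")
  vapply(seq_len(nrow(n)), function(i)
    .hweExactOne(n[i, 1L], n[i, 2L], n[i, 3L]), numeric(1))
}

.hweExactOne <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2L * nAA + nAB
  nB <- 2L * n - nA
  nr <- min(nA, nB)                      # rare allele count
  if (nr == 0L) return(1)
  hets <- seq(nr %% 2L, nr, by = 2L)
  ## log P(het = h | n, nA): multinomial genotype probability conditioned on
  ## allele counts
  logp <- vapply(hets, function(h) {
    haa <- (nA - h) / 2
    hbb <- (nB - h) / 2
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

## Per-site genotype counts from a dosage matrix with NA for missing.
.genotypeCounts <- function(D) {
  notNA <- !is.na(D)
  cbind(nHomRef = colSums(D == 0, na.rm = TRUE),
        nHet = colSums(D == 1, na.rm = TRUE),
        nHomAlt = colSums(D == 2, na.rm = TRUE),
        nCalled = colSums(notNA))
}

#' Filter variants on call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Applies the three genotype-level filters in a fixed order (call rate,
#' then MAF, then HWE), each on the survivors of the previous one, with
#' strict-inequality removal: a variant is removed when call rate <
#' `callRateMin`, MAF < `mafMin`, or HWE exact p < `hwePMin`.
#'
#' @param panel a [HaplotypePanel-class].
#' @param thresholds a [qcThresholds()] list.
#' @return `list(panel, report)` where `report` is a `QcReport` with
#'   per-filter removal counts; removals plus retained always equal the
#'   input variant count.
#' @export
filterVariants <- function(panel, thresholds = qcThresholds()) {
  stopifnot(is(panel, "HaplotypePanel"), inherits(thresholds, "QcThresholds"))
  D <- dosageMatrix(panel)
  m <- ncol(D)
  keep <- rep(TRUE, m)

  callRate <- colMeans(!is.na(D))
  failCall <- callRate < thresholds$callRateMin
  keep[failCall] <- FALSE

  freq <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  failMaf <- keep & (maf < thresholds$mafMin)
  keep[failMaf] <- FALSE

  failHwe <- rep(FALSE, m)
  if (any(keep)) {
    gc <- .genotypeCounts(D[, keep, drop = FALSE])
    p <- hweExactTest(gc[, "nHomRef"], gc[, "nHet"], gc[, "nHomAlt"])
    failHwe[keep] <- p < thresholds$hwePMin
    keep[failHwe] <- FALSE
  }

  if (!any(keep)) warning("no variants survive filtering")
  report <- structure(list(
    input = m,
    removedCallRate = sum(failCall),
    removedMaf = sum(failMaf),
    removedHwe = sum(failHwe),
    retained = sum(keep),
    retainedSamples = nSamples(panel),
    thresholds = thresholds,
    order = c("callRate", "maf", "hwe")), class = "QcReport")
  list(panel = panel[, keep], report = report)
}

#' @export
print.QcReport <- function(x, ...) {
  cat("QcReport:", x$input, "variants in;",
      x$retained, "retained (", x$retainedSamples, "samples )\n")
  cat("  removed: call rate", x$removedCallRate,
      "| MAF", x$removedMaf, "| HWE", x$removedHwe, "\n")
  invisible(x)
}

#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation on pairwise-complete genotypes. Defined as 0
#' when either vector has no variance (such a pair cannot be pruned on).
#'
#' @param x,y equal-length dosage vectors (NA = missing).
#' @return squared correlation in [0, 1].
#' @export
ldR2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  cor(x, y)^2
}

#' Greedy sliding-window LD pruning
#'
#' Scans windows of `ldWindow` variants (sliding by `ldStep`) along each
#' chromosome; within a window, every pair with r-squared strictly above
#' `ldR2Max` loses its lower-MAF member (tie: the later position is
#' removed). Passes repeat until no further removal, so the result is
#' deterministic and, by construction, no surviving within-window pair
#' exceeds the threshold.
#'
#' @param panel a [HaplotypePanel-class].
#' @param thresholds a [qcThresholds()] list.
#' @return sorted integer indices (into the panel's sites) of the retained
#'   variants.
#' @export
ldPrune <- function(panel, thresholds = qcThresholds()) {
  stopifnot(is(panel, "HaplotypePanel"))
  D <- dosageMatrix(panel)
  freq <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- rep(TRUE, ncol(D))
  win <- thresholds$ldWindow
  step <- thresholds$ldStep

  for (cc in unique(panel@chrom)) {
    onChrom <- which(panel@chrom == cc)
    repeat {
      cur <- onChrom[keep[onChrom]]
      removed <- FALSE
      starts <- seq(1L, max(1L, length(cur) - 1L), by = step)
      for (s in starts) {
        idx <- cur[s:min(s + win - 1L, length(cur))]
        idx <- idx[keep[idx]]
        if (length(idx) < 2L) next
        r2 <- suppressWarnings(
          cor(D[, idx, drop = FALSE], use = "pairwise.complete.obs")^2)
        r2[!is.finite(r2)] <- 0
        r2[lower.tri(r2, diag = TRUE)] <- 0
        pairs <- which(r2 > thresholds$ldR2Max, arr.ind = TRUE)
        if (!nrow(pairs)) next
        ## deterministic order: strongest LD first, then first index
        ord <- order(-r2[pairs], pairs[, 1L], pairs[, 2L])
        for (k in ord) {
          i <- idx[pairs[k, 1L]]
          j <- idx[pairs[k, 2L]]
          if (!keep[i] || !keep[j]) next
          drop <- if (maf[i] < maf[j]) i
                  else if (maf[j] < maf[i]) j
                  else if (panel@pos[i] > panel@pos[j]) i else j
          keep[drop] <- FALSE
          removed <- TRUE
        }
      }
      if (!removed) break
    }
  }
  which(keep)
}
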