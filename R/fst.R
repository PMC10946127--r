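## Weir-Cockerham (1984) two-population FST, overlapping genomic windows,
## and windowed FST scans.

#' Per-site Weir-Cockerham variance components and theta
#'
#' Two-population moment estimator: from per-population genotype counts it
#' computes the among-population (a), among-individual (b) and
#' within-individual (c) variance components and theta = a / (a + b + c).
#' Theta can be slightly negative (property of the estimator) and is
#' undefined (NA) when the site is monomorphic across both populations
#' (a + b + c = 0).
#'
#' @param counts1,counts2 genotype counts per population: a length-3 vector
#'   `(nHomRef, nHet, nHomAlt)` or a sites x 3 matrix.
#' @return a `data.frame` with columns `a`, `b`, `c`, `theta` (one row per
#'   site).
#' @examples
#' wcFst(c(10, 0, 0), c(0, 0, 10))$theta  # 1
#' @export
wcFst <- function(counts1, counts2) {
  if (is.null(dim(counts1))) counts1 <- matrix(counts1, ncol = 3L)
  if (is.null(dim(counts2))) counts2 <- matrix(counts2, ncol = 3L)
  stopifnot(ncol(counts1) == 3L, ncol(counts2) == 3L,
            nrow(counts1) == nrow(counts2),
            all(counts1 >= 0), all(counts2 >= 0))
  n1 <- rowSums(counts1)
  n2 <- rowSums(counts2)
  empty <- n1 == 0 | n2 == 0
  if (all(empty))
    stop("each population needs at least one genotyped sample per site")
  n1[empty] <- NA_real_
  p1 <- (2 * counts1[, 3L] + counts1[, 2L]) / (2 * n1)
  p2 <- (2 * counts2[, 3L] + counts2[, 2L]) / (2 * n2)
  h1 <- counts1[, 2L] / n1
  h2 <- counts2[, 2L] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(is.na(tot) | tot == 0, NA_real_, a / tot)
  data.frame(a = a, b = b, c = cc, theta = theta)
}

#' Overlapping genomic windows
#'
#' Tiles each chromosome with 1-based windows `[1 + k*step,
#' k*step + span]`, the last window truncated at the chromosome end.
#' Defaults give the 50-kb windows with 25-kb overlap used by the scans.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param span window span in bp.
#' @param step distance between window starts in bp; `span < step`
#'   (non-overlapping gaps) is rejected.
#' @return a `data.frame(chrom, start, end)`, with attributes `span` and
#'   `step`.
#' @examples
#' makeWindows(c(chr1 = 1e5))
#' @export
makeWindows <- function(chromLengths, span = 50000, step = 25000) {
  stopifnot(all(chromLengths > 0), span >= 1, step >= 1)
  if (span < step) stop("span must be >= step (windows may not leave gaps)")
  if (is.null(names(chromLengths)))
    names(chromLengths) <- sprintf("chr%d", seq_along(chromLengths))
  out <- do.call(rbind, lapply(names(chromLengths), function(cc) {
    L <- chromLengths[[cc]]
    starts <- seq(1, L, by = step)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + span - 1, L))
  }))
  rownames(out) <- NULL
  attr(out, "span") <- span
  attr(out, "step") <- step
  out
}

## Map each site to the (possibly several, for overlapping tilings) windows
## containing it. Returns a two-column matrix (site index, window row).
.siteWindowMap <- function(chrom, pos, windows) {
  span <- attr(windows, "span")
  step <- attr(windows, "step")
  res <- vector("list", length(unique(windows$chrom)))
  names(res) <- unique(windows$chrom)
  for (cc in names(res)) {
    sIdx <- which(chrom == cc)
    wIdx <- which(windows$chrom == cc)
    if (!length(sIdx) || !length(wIdx)) next
    ## window k (0-based) holds pos P iff 1 + k*step <= P <= k*step + span
    kmax <- length(wIdx) - 1L
    p <- pos[sIdx]
    kLo <- pmax(0, ceiling((p - span) / step))
    kHi <- pmin(kmax, floor((p - 1) / step))
    nK <- pmax(0L, kHi - kLo + 1L)
    site <- rep(sIdx, nK)
    k <- unlist(lapply(seq_along(p), function(i)
      if (nK[i] > 0L) kLo[i]:kHi[i] else integer()), use.names = FALSE)
    res[[cc]] <- cbind(site = site, window = wIdx[k + 1L])
  }
  do.call(rbind, res)
}

.newWindowStats <- function(windows, nSnps, stat, method,
                            extra = NULL) {
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_snps = nSnps, stat = stat)
  if (!is.null(extra)) out <- cbind(out, extra)
  out$p <- NA_real_
  out$signed_log10p <- NA_real_
  out$significant <- NA
  attr(out, "span") <- attr(windows, "span")
  attr(out, "step") <- attr(windows, "step")
  attr(out, "method") <- method
  class(out) <- c("WindowStats", "data.frame")
  out
}

#' Windowed Weir-Cockerham FST between two sample groups
#'
#' Computes per-site theta for the contrast and averages it within each
#' window. The primary statistic is the arithmetic mean of defined per-site
#' theta ("average FST"); the ratio-of-sums estimator
#' `sum(a) / sum(a + b + c)` is emitted alongside as `stat_ratio`. Sites
#' monomorphic across both groups are excluded rather than counted as zero,
#' and windows without informative SNPs carry `NA` (excluded from ranking).
#'
#' @param panel a [HaplotypePanel-class].
#' @param samplesA,samplesB disjoint character vectors of sample ids.
#' @param windows tiling from [makeWindows()].
#' @return a `WindowStats` data.frame (`chrom`, `start`, `end`, `n_snps`,
#'   `stat`, `stat_ratio`, and empty significance columns for
#'   [empiricalP()]).
#' @export
windowedFst <- function(panel, samplesA, samplesB, windows) {
  stopifnot(is(panel, "HaplotypePanel"),
            length(samplesA) > 0, length(samplesB) > 0,
            !any(samplesA %in% samplesB))
  D <- dosageMatrix(panel)
  cA <- .genotypeCounts(D[match(samplesA, panel@samples), , drop = FALSE])
  cB <- .genotypeCounts(D[match(samplesB, panel@samples), , drop = FALSE])
  comp <- wcFst(cA[, 1:3], cB[, 1:3])
  map <- .siteWindowMap(panel@chrom, panel@pos, windows)

  nW <- nrow(windows)
  theta <- comp$theta[map[, "site"]]
  wfac <- factor(map[, "window"], levels = seq_len(nW))
  ok <- !is.na(theta)
  nSnps <- as.integer(table(wfac[ok]))
  meanTheta <- as.numeric(tapply(theta[ok], wfac[ok], mean, default = NA))
  sumA <- as.numeric(tapply(comp$a[map[, "site"]][ok], wfac[ok], sum,
                            default = NA))
  sumTot <- as.numeric(tapply(
    (comp$a + comp$b + comp$c)[map[, "site"]][ok], wfac[ok], sum,
    default = NA))
  ratio <- ifelse(is.na(sumTot) | sumTot == 0, NA_real_, sumA / sumTot)
  .newWindowStats(windows, nSnps, meanTheta, "fst",
                  extra = data.frame(stat_ratio = ratio))
}
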