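## Empirical window significance by genome-wide ranking, and cross-method
## overlap of significant windows.

#' Empirical rank p-values for windowed statistics
#'
#' Ranks windows by their statistic and divides the rank by the number of
#' windows with a defined statistic. One-sided (FST-style): rank 1 is the
#' largest value. Two-sided (XP-EHH-style): windows with non-negative
#' statistic are ranked descending, negative ones ascending, each tail
#' ranked over all N windows; the significance column `signed_log10p`
#' carries `-log10(p)` with the sign of the statistic. Tied values share
#' the worst (largest) rank of their block, so fully tied scans are never
#' significant. A window is flagged significant when its empirical p is at
#' most `topFrac`, i.e. it lies in the top `topFrac` fraction of its tail
#' (with all values distinct, one-sided, exactly `floor(topFrac * N)`
#' windows are flagged).
#'
#' @param stats a `WindowStats` data.frame with a `stat` column.
#' @param twoSided ranking mode (see above).
#' @param topFrac retained fraction (default 0.01, the "top 1 percent").
#' @return `stats` with `p`, `signed_log10p` and `significant` filled.
#' @export
empiricalP <- function(stats, twoSided = FALSE, topFrac = 0.01) {
  stopifnot(is.data.frame(stats), "stat" %in% names(stats),
            topFrac > 0, topFrac <= 1)
  x <- stats$stat
  def <- !is.na(x)
  N <- sum(def)
  if (N == 0L) stop("no window has a defined statistic")
  p <- rep(NA_real_, length(x))
  if (!twoSided) {
    r <- rank(-x[def], ties.method = "max")
    p[def] <- r / N
    stats$signed_log10p <- -log10(p)
  } else {
    rUp <- rank(-x[def], ties.method = "max") / N
    rDn <- rank(x[def], ties.method = "max") / N
    up <- x[def] >= 0
    p[def] <- ifelse(up, rUp, rDn)
    s <- rep(NA_real_, length(x))
    s[def] <- ifelse(up, -log10(rUp), log10(rDn))
    stats$signed_log10p <- s
  }
  stats$p <- p
  stats$significant <- !is.na(p) & p <= topFrac
  attr(stats, "topFrac") <- topFrac
  attr(stats, "twoSided") <- twoSided
  stats
}

#' Overlap between two sets of significant windows
#'
#' Counts windows flagged significant by both scans and reports the overlap
#' under the three defensible denominators (union, set A, set B), since a
#' single "percent overlap" is ambiguous.
#'
#' @param statsA,statsB `WindowStats` over the identical window tiling,
#'   with significance columns filled by [empiricalP()].
#' @return a list: `nA`, `nB`, `nIntersect`, `pctUnion`, `pctOfA`,
#'   `pctOfB` (percentages; 0 when the denominator is empty).
#' @export
overlapWindows <- function(statsA, statsB) {
  tilingA <- statsA[c("chrom", "start", "end")]
  tilingB <- statsB[c("chrom", "start", "end")]
  if (!isTRUE(all.equal(tilingA, tilingB, check.attributes = FALSE)))
    stop("window tilings differ; overlap requires identical windows")
  a <- which(statsA$significant %in% TRUE)
  b <- which(statsB$significant %in% TRUE)
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  list(nA = length(a), nB = length(b), nIntersect = i,
       pctUnion = pct(i, u), pctOfA = pct(i, length(a)),
       pctOfB = pct(i, length(b)))
}
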