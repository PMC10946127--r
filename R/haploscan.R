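## Haplotype-based selection scans: EHH decay curves, integrated haplotype
## homozygosity (iHH), and the cross-population XP-EHH statistic. The inner
## haplotype-grouping scan is compiled (src/ehh.cpp).

.hapRows <- function(panel, samples) {
  i <- match(samples, panel@samples)
  if (anyNA(i)) stop("unknown sample id(s): ",
                     paste(samples[is.na(i)], collapse = ", "))
  as.vector(rbind(2L * i - 1L, 2L * i))
}

.chromId <- function(panel) as.integer(factor(panel@chrom,
                                              levels = unique(panel@chrom)))

#' Extended haplotype homozygosity curve around a core site
#'
#' Among the haplotypes of `samples` carrying `allele` at the core site,
#' EHH at a flanking site is the probability that two randomly chosen
#' carrier haplotypes are identical over the whole stretch from the core to
#' that site: `sum(choose(n_k, 2)) / choose(n, 2)` over distinct extended
#' haplotypes. The curve starts at 1 at the core and is non-increasing
#' outward; scanning in each direction stops once EHH drops below `cutoff`
#' (that point is recorded) or at the chromosome end.
#'
#' @param panel a [HaplotypePanel-class] (phased).
#' @param samples sample ids of the population scanned.
#' @param core site index of the core locus.
#' @param allele core allele (0 or 1); needs at least two carriers.
#' @param cutoff EHH value below which the outward scan stops.
#' @return an object of class `EhhCurve`: `core`, `corePos`, `allele`,
#'   `nCarriers`, and `left`/`right` data.frames `(site, pos, ehh)`
#'   ordered outward from the core.
#' @export
ehh <- function(panel, samples, core, allele = 1L, cutoff = 0.05) {
  stopifnot(is(panel, "HaplotypePanel"), core >= 1, core <= nSites(panel),
            allele %in% c(0L, 1L))
  rows <- .hapRows(panel, samples)
  carriers <- rows[panel@haplotypes[rows, core] == allele]
  if (length(carriers) < 2L)
    stop("EHH undefined: fewer than two carriers of the core allele")
  res <- .cppEhhCurve(panel@haplotypes, carriers, .chromId(panel),
                      as.integer(core), cutoff)
  side <- function(sites, vals)
    data.frame(site = sites, pos = panel@pos[sites], ehh = vals)
  structure(list(core = as.integer(core), corePos = panel@pos[core],
                 allele = as.integer(allele),
                 nCarriers = length(carriers), cutoff = cutoff,
                 left = side(res$leftSites, res$leftEhh),
                 right = side(res$rightSites, res$rightEhh)),
            class = "EhhCurve")
}

#' @export
print.EhhCurve <- function(x, ...) {
  cat("EhhCurve: core site", x$core, "at", x$corePos, "bp, allele",
      x$allele, sprintf("(%d carriers)\n", x$nCarriers))
  cat("  extends", nrow(x$left), "sites left,", nrow(x$right),
      "sites right (cutoff", x$cutoff, ")\n")
  invisible(x)
}

#' Integrated haplotype homozygosity of an EHH curve
#'
#' Trapezoidal integral of the EHH decay curve over physical distance (bp),
#' anchored at EHH = 1 at the core and summed over both directions. A
#' degenerate curve with no flanking points integrates to 0.
#'
#' @param curve an [ehh()] result.
#' @return non-negative scalar (bp-weighted homozygosity).
#' @export
ihh <- function(curve) {
  stopifnot(inherits(curve, "EhhCurve"))
  side <- function(df) {
    if (!nrow(df)) return(0)
    p <- c(curve$corePos, df$pos)
    v <- c(1, df$ehh)
    sum(0.5 * (v[-1] + v[-length(v)]) * abs(diff(p)))
  }
  side(curve$left) + side(curve$right)
}

## Population-level iHH at each core site (allele-count weighted over the
## two core alleles; see src/ehh.cpp).
.popIhh <- function(panel, samples, sites, cutoff) {
  .cppIhhSites(panel@haplotypes, .hapRows(panel, samples), .chromId(panel),
               as.numeric(panel@pos), as.integer(sites), cutoff)
}

#' Cross-population extended haplotype homozygosity (XP-EHH) scan
#'
#' For each core site, computes the population-level iHH in each group
#' (per-allele iHH among carriers, combined weighted by allele count) and
#' the unstandardized score `ln(iHH_A / iHH_B)`. Scores are standardized
#' genome-wide (mean 0, SD 1 over defined scores); positive values indicate
#' reduced haplotype diversity — recent selection — in `samplesA`, negative
#' in `samplesB`. With a window tiling, the windowed statistic is the mean
#' standardized score of the sites in each window.
#'
#' @param panel a phased [HaplotypePanel-class].
#' @param samplesA,samplesB disjoint sample-id groups.
#' @param windows optional tiling from [makeWindows()].
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param minMaf minimum pooled minor allele frequency for a site to be
#'   used as a core (default 0.05).
#' @return list with `sites` (per-site data.frame: `chrom`, `pos`, `site`,
#'   `ihhA`, `ihhB`, `raw`, `std`) and `windows` (a `WindowStats`, or NULL
#'   when no tiling was supplied).
#' @export
xpehh <- function(panel, samplesA, samplesB, windows = NULL,
                  cutoff = 0.05, minMaf = 0.05) {
  stopifnot(is(panel, "HaplotypePanel"), !any(samplesA %in% samplesB))
  rowsAll <- .hapRows(panel, c(samplesA, samplesB))
  freq <- colMeans(panel@haplotypes[rowsAll, , drop = FALSE])
  cores <- which(pmin(freq, 1 - freq) >= minMaf)
  if (!length(cores)) stop("no core site passes the pooled MAF filter")
  ihhA <- .popIhh(panel, samplesA, cores, cutoff)
  ihhB <- .popIhh(panel, samplesB, cores, cutoff)
  raw <- ifelse(!is.na(ihhA) & !is.na(ihhB) & ihhA > 0 & ihhB > 0,
                log(ihhA / ihhB), NA_real_)
  def <- !is.na(raw)
  if (!any(def)) stop("no site has a defined XP-EHH score")
  sdRaw <- sd(raw[def])
  std <- rep(NA_real_, length(raw))
  std[def] <- if (sdRaw > 0) (raw[def] - mean(raw[def])) / sdRaw else 0
  sites <- data.frame(chrom = panel@chrom[cores], pos = panel@pos[cores],
                      site = cores, ihhA = ihhA, ihhB = ihhB,
                      raw = raw, std = std)
  win <- NULL
  if (!is.null(windows)) {
    map <- .siteWindowMap(sites$chrom, sites$pos, windows)
    wfac <- factor(map[, "window"], levels = seq_len(nrow(windows)))
    sc <- sites$std[map[, "site"]]
    ok <- !is.na(sc)
    nSnps <- as.integer(table(wfac[ok]))
    meanStd <- as.numeric(tapply(sc[ok], wfac[ok], mean, default = NA))
    win <- .newWindowStats(windows, nSnps, meanStd, "xpehh")
  }
  list(sites = sites, windows = win)
}
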