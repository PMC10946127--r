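## Ground-truth signal injection: hard sweeps for the haplotype scans and
## environmental clines / polygenic traits for the ordination scans. Both
## record their specification in the panel metadata so recovery tests never
## re-derive the truth.

#' Inject a hard selective sweep into target populations
#'
#' Emulates a recent hard sweep: within the target populations, a fraction
#' of haplotypes is replaced by identical copies of one donor haplotype
#' across `[corePos - span/2, corePos + span/2]`, forcing extended
#' haplotype homozygosity over the span. Other populations and sites
#' outside the span are untouched.
#'
#' @param panel a [HaplotypePanel-class].
#' @param populations population ids carrying the sweep (requires
#'   `metadata$populations`).
#' @param chrom chromosome of the sweep core.
#' @param corePos core position in bp (must lie on `chrom`'s site range).
#' @param carrierFraction fraction of target haplotypes replaced, in (0,1].
#' @param span sweep span in bp; truncated (with a warning) at chromosome
#'   ends.
#' @param seed seed for the choice of donor and carriers.
#' @return the modified panel, with the sweep appended to
#'   `metadata$sweeps`.
#' @export
injectSweep <- function(panel, populations, chrom, corePos,
                        carrierFraction = 0.8, span = 5e5, seed = 1L) {
  stopifnot(is(panel, "HaplotypePanel"),
            carrierFraction > 0, carrierFraction <= 1, span > 0)
  pops <- panel@metadata$populations
  if (is.null(pops)) stop("panel metadata lacks a 'populations' mapping")
  onChrom <- which(panel@chrom == chrom)
  if (!length(onChrom)) stop("unknown chromosome: ", chrom)
  rng <- range(panel@pos[onChrom])
  if (corePos < rng[1] || corePos > rng[2])
    stop("corePos outside the genotyped range of ", chrom)
  lo <- corePos - span / 2
  hi <- corePos + span / 2
  chromLen <- panel@metadata$chromLength
  if (lo < 1 || (!is.null(chromLen) && hi > chromLen)) {
    warning("sweep span truncated at chromosome end")
    lo <- max(lo, 1)
    if (!is.null(chromLen)) hi <- min(hi, chromLen)
  }
  sites <- onChrom[panel@pos[onChrom] >= lo & panel@pos[onChrom] <= hi]

  targetSamples <- which(pops %in% populations)
  if (!length(targetSamples)) stop("no samples in target populations")
  hapRows <- as.vector(rbind(2L * targetSamples - 1L, 2L * targetSamples))
  hap <- panel@haplotypes
  .withSeed(seed, {
    donor <- hap[sample(hapRows, 1L), sites]
    nCarrier <- max(1L, round(carrierFraction * length(hapRows)))
    carriers <- sample(hapRows, nCarrier)
    hap[carriers, sites] <- rep(donor, each = nCarrier)
  })
  panel@haplotypes <- hap
  panel@metadata$sweeps <- c(panel@metadata$sweeps, list(list(
    populations = populations, chrom = chrom, corePos = corePos,
    carrierFraction = carrierFraction, span = hi - lo,
    siteRange = range(sites))))
  validObject(panel)
  panel
}

#' Inject an environmental allele-frequency cline at one locus
#'
#' Rewrites one locus so each population's alternate-allele frequency is
#' `logistic(logit(baseline) + slope * z)`, with `z` the predictor
#' standardized across populations. Haplotypes are re-drawn at that locus
#' only; all other sites are untouched.
#'
#' @param panel a [HaplotypePanel-class].
#' @param frame metadata from [simulateMetadata()].
#' @param locus site index in the panel.
#' @param predictor name of the environmental predictor column driving the
#'   cline.
#' @param slope cline steepness on the logit scale per standardized
#'   predictor unit.
#' @param baseline frequency at the predictor mean, in (0,1).
#' @param seed seed for the haplotype redraw.
#' @return the modified panel, with the cline appended to
#'   `metadata$clines`.
#' @export
injectEnvCline <- function(panel, frame, locus, predictor, slope,
                           baseline = 0.5, seed = 1L) {
  stopifnot(is(panel, "HaplotypePanel"), baseline > 0, baseline < 1)
  if (locus < 1L || locus > nSites(panel)) stop("locus index out of range")
  if (!predictor %in% names(frame)) stop("unknown predictor: ", predictor)
  popTab <- unique(frame[c("population_id", predictor)])
  z <- as.numeric(scale(popTab[[predictor]]))
  q <- plogis(qlogis(baseline) + slope * z)
  names(q) <- popTab$population_id
  pops <- rep(frame$population_id, each = 2L)
  .withSeed(seed, {
    panel@haplotypes[, locus] <-
      rbinom(length(pops), 1L, q[pops])
  })
  if (!is.null(panel@metadata$popFreq))
    panel@metadata$popFreq[names(q), locus] <- q
  panel@metadata$clines <- c(panel@metadata$clines, list(list(
    locus = locus, predictor = predictor, slope = slope,
    baseline = baseline)))
  validObject(panel)
  panel
}

#' Simulate quantitative traits with genetic and environmental effects
#'
#' Each trait is an additive QTL sum plus a linear environmental component
#' plus Gaussian noise:
#' `trait = sum(effect * dosage) + sum(coef * predictor) + N(0, residualSd)`.
#'
#' @param panel a [HaplotypePanel-class] providing QTL dosages.
#' @param frame metadata from [simulateMetadata()].
#' @param qtlEffects `data.frame(trait, locus, effect)`; loci are site
#'   indices in the panel. May be empty/NULL for purely environmental
#'   traits.
#' @param envEffects `data.frame(trait, predictor, coef)`; may be
#'   empty/NULL.
#' @param residualSd residual standard deviation, scalar or named per
#'   trait.
#' @param seed integer seed.
#' @return `frame` with the five trait columns filled; ground truth is
#'   attached as attribute `traitTruth`.
#' @export
simulateTraits <- function(panel, frame, qtlEffects = NULL, envEffects = NULL,
                           residualSd = 1, seed = 1L) {
  stopifnot(is(panel, "HaplotypePanel"))
  traits <- attr(frame, "traits")
  if (is.null(traits)) traits <- .traitNames()
  if (!is.null(qtlEffects) && nrow(qtlEffects)) {
    if (any(qtlEffects$locus < 1L | qtlEffects$locus > nSites(panel)))
      stop("QTL locus index out of range")
    if (!all(qtlEffects$trait %in% traits)) stop("unknown trait in qtlEffects")
  }
  if (!is.null(envEffects) && nrow(envEffects) &&
      !all(envEffects$predictor %in% names(frame)))
    stop("unknown predictor in envEffects")
  if (length(residualSd) == 1L)
    residualSd <- setNames(rep(residualSd, length(traits)), traits)
  D <- dosageMatrix(panel)
  D[is.na(D)] <- 0                                 # masked genotypes carry 0
  .withSeed(seed, {
    for (tr in traits) {
      y <- rep(0, nrow(frame))
      if (!is.null(qtlEffects)) {
        qe <- qtlEffects[qtlEffects$trait == tr, , drop = FALSE]
        if (nrow(qe))
          y <- y + as.numeric(D[, qe$locus, drop = FALSE] %*% qe$effect)
      }
      if (!is.null(envEffects)) {
        ee <- envEffects[envEffects$trait == tr, , drop = FALSE]
        if (nrow(ee))
          y <- y + as.numeric(
            as.matrix(frame[ee$predictor]) %*% ee$coef)
      }
      sdv <- residualSd[[tr]]
      if (sdv > 0) y <- y + rnorm(length(y), 0, sdv)
      frame[[tr]] <- y
    }
  })
  attr(frame, "traitTruth") <- list(qtlEffects = qtlEffects,
                                    envEffects = envEffects,
                                    residualSd = residualSd, seed = seed)
  frame
}
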