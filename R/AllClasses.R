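#' @import methods
#' @importFrom stats cor rbinom rbeta rnorm runif setNames plogis qlogis
#'   pnorm phyper p.adjust complete.cases sd var quantile
NULL

#' Simulation configuration for a gradient-by-agroecology population design
#'
#' Holds the parameters of the synthetic structured-population generator:
#' a hierarchical sampling design of environmental gradients, each crossed
#' with elevation-defined agroecologies (lowland/midaltitude/highland), with
#' several village-level populations per gradient-agroecology cell.
#'
#' @slot nGradients number of environmental gradients.
#' @slot agroecologies ordered agroecology labels (low to high elevation).
#' @slot popsPerCell populations per gradient-by-agroecology cell.
#' @slot samplesPerPop diploid individuals sampled per population.
#' @slot nChromosomes number of autosomes.
#' @slot chromLength chromosome length in base pairs.
#' @slot nSnps total number of biallelic SNPs across chromosomes.
#' @slot founderHaplotypes number of founder haplotypes for the mosaic model.
#' @slot recombRate per-bp probability that the founder mosaic switches
#'   between adjacent template haplotypes (cumulative, not per-generation).
#' @slot fstLevel Balding-Nichols differentiation parameter F in [0,1).
#' @slot missingRate per-genotype missingness probability.
#' @slot seed integer seed controlling all randomness of the generator.
#' @seealso [simConfig()] for the validated constructor with defaults.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nGradients = "integer",
  agroecologies = "character",
  popsPerCell = "integer",
  samplesPerPop = "integer",
  nChromosomes = "integer",
  chromLength = "numeric",
  nSnps = "integer",
  founderHaplotypes = "integer",
  recombRate = "numeric",
  fstLevel = "numeric",
  missingRate = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(nGradients = object@nGradients, popsPerCell = object@popsPerCell,
           samplesPerPop = object@samplesPerPop,
           nChromosomes = object@nChromosomes, nSnps = object@nSnps,
           founderHaplotypes = object@founderHaplotypes)
  if (any(cnt < 1L)) {
    msg <- c(msg, paste("counts must be >= 1:",
                        paste(names(cnt)[cnt < 1L], collapse = ", ")))
  }
  if (length(object@agroecologies) < 1L || anyDuplicated(object@agroecologies))
    msg <- c(msg, "agroecologies must be distinct labels")
  if (!all(object@agroecologies %in% names(.agroBands())))
    msg <- c(msg, paste("unknown agroecology; known:",
                        paste(names(.agroBands()), collapse = ", ")))
  if (object@fstLevel < 0 || object@fstLevel >= 1)
    msg <- c(msg, "fstLevel must lie in [0, 1)")
  if (object@recombRate < 0 || object@recombRate > 1)
    msg <- c(msg, "recombRate must lie in [0, 1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@chromLength < 1)
    msg <- c(msg, "chromLength must be positive")
  if (length(msg)) msg else TRUE
})

## Elevation bands (m above sea level) of the conventional Ethiopian
## agroecological classification used by the sampling design.
.agroBands <- function() {
  list(lowland = c(400, 1800), midaltitude = c(1800, 2400),
       highland = c(2400, 3500))
}

#' Construct a simulation configuration
#'
#' Defaults mirror the sampling design the generator emulates: four
#' environmental gradients, each crossed with three elevation-defined
#' agroecologies, two village populations per cell and 18 diploids per
#' population, genotyped at 20,000 SNPs on two 10-Mb autosomes.
#'
#' @param nGradients number of gradients (default 4).
#' @param agroecologies ordered agroecology labels; each has a fixed
#'   elevation band (lowland 400-1800, midaltitude 1800-2400, highland
#'   2400-3500 m.a.s.l.).
#' @param popsPerCell populations per gradient-agroecology cell (default 2).
#' @param samplesPerPop diploids per population (default 18).
#' @param nChromosomes,chromLength genome layout (default 2 x 10 Mb).
#' @param nSnps total SNP count (default 20000).
#' @param founderHaplotypes founder templates for the mosaic model.
#' @param recombRate per-bp mosaic switch probability.
#' @param fstLevel Balding-Nichols F in [0,1) (default 0.02, the scale of
#'   between-gradient differentiation in village-chicken data).
#' @param missingRate per-genotype missingness probability (default 0).
#' @param seed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSnps = 500L, samplesPerPop = 5L, seed = 1L)
#' @export
simConfig <- function(nGradients = 4L,
                      agroecologies = c("lowland", "midaltitude", "highland"),
                      popsPerCell = 2L, samplesPerPop = 18L,
                      nChromosomes = 2L, chromLength = 1e7, nSnps = 20000L,
                      founderHaplotypes = 30L, recombRate = 1e-6,
                      fstLevel = 0.02, missingRate = 0, seed = 1L) {
  new("SimConfig",
      nGradients = as.integer(nGradients),
      agroecologies = as.character(agroecologies),
      popsPerCell = as.integer(popsPerCell),
      samplesPerPop = as.integer(samplesPerPop),
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.numeric(chromLength),
      nSnps = as.integer(nSnps),
      founderHaplotypes = as.integer(founderHaplotypes),
      recombRate = as.numeric(recombRate),
      fstLevel = as.numeric(fstLevel),
      missingRate = as.numeric(missingRate),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGradients, "gradients x",
      length(object@agroecologies), "agroecologies x",
      object@popsPerCell, "pops/cell,",
      object@samplesPerPop, "diploids/pop\n")
  cat("  genome:", object@nChromosomes, "chromosomes x",
      format(object@chromLength, big.mark = ","), "bp,",
      object@nSnps, "SNPs,", object@founderHaplotypes, "founders\n")
  cat("  fstLevel:", object@fstLevel, " recombRate:", object@recombRate,
      " missingRate:", object@missingRate, " seed:", object@seed, "\n")
})

#' Phased biallelic haplotype panel
#'
#' The substrate of all scans: a matrix of phased 0/1 haplotypes (two rows
#' per diploid sample), site coordinates (1-based, strictly increasing
#' within chromosome), ref/alt alleles and a diploid-level missingness mask.
#' Ground truth injected by the simulator (per-population target allele
#' frequencies, sweep and cline specifications) travels in `metadata`.
#'
#' @slot chrom chromosome id per site.
#' @slot pos 1-based physical position per site.
#' @slot ref,alt reference / alternate allele per site.
#' @slot haplotypes integer matrix of 0/1, `2 * nSamples` rows x sites.
#' @slot samples sample identifiers (one per diploid).
#' @slot missing logical matrix, samples x sites; TRUE marks a missing
#'   diploid genotype (haplotype entries retain imputed phase).
#' @slot metadata free-form list (simulation ground truth, provenance).
#' @exportClass HaplotypePanel
setClass("HaplotypePanel", representation(
  chrom = "character", pos = "integer",
  ref = "character", alt = "character",
  haplotypes = "matrix", samples = "character",
  missing = "matrix", metadata = "list"
))

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  m <- length(object@pos)
  n <- length(object@samples)
  if (length(object@chrom) != m || length(object@ref) != m ||
      length(object@alt) != m)
    msg <- c(msg, "chrom/pos/ref/alt lengths disagree")
  if (nrow(object@haplotypes) != 2L * n)
    msg <- c(msg, "haplotype matrix must have two rows per sample")
  if (ncol(object@haplotypes) != m)
    msg <- c(msg, "haplotype matrix columns must match site count")
  if (!all(object@haplotypes %in% c(0L, 1L)))
    msg <- c(msg, "haplotype entries must be 0 or 1")
  if (!identical(dim(object@missing), c(n, m)))
    msg <- c(msg, "missing mask must be samples x sites")
  bad <- vapply(split(object@pos, object@chrom),
                function(p) is.unsorted(p, strictly = TRUE), logical(1))
  if (any(bad))
    msg <- c(msg, "positions must be strictly increasing within chromosome")
  if (length(msg)) msg else TRUE
})

#' Build a HaplotypePanel
#'
#' @param chrom,pos,ref,alt per-site fields; sites must be ordered by
#'   chromosome then position.
#' @param haplotypes 0/1 integer matrix, two consecutive rows per sample.
#' @param samples sample ids.
#' @param missing optional samples x sites logical mask (default none).
#' @param metadata optional list.
#' @return a [HaplotypePanel-class].
#' @export
HaplotypePanel <- function(chrom, pos, ref, alt, haplotypes, samples,
                           missing = NULL, metadata = list()) {
  if (is.null(missing))
    missing <- matrix(FALSE, length(samples), length(pos))
  storage.mode(haplotypes) <- "integer"
  new("HaplotypePanel", chrom = as.character(chrom), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      haplotypes = haplotypes, samples = as.character(samples),
      missing = missing, metadata = metadata)
}

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", length(object@samples), "samples,",
      length(object@pos), "sites on",
      length(unique(object@chrom)), "chromosome(s)\n")
  miss <- mean(object@missing)
  cat("  missing genotypes:", sprintf("%.3f%%", 100 * miss), "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' @describeIn HaplotypePanel number of diploid samples.
#' @param x,object a `HaplotypePanel`.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "HaplotypePanel", function(x) length(x@samples))

#' @describeIn HaplotypePanel number of sites.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setMethod("nSites", "HaplotypePanel", function(x) length(x@pos))

#' @describeIn HaplotypePanel sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "HaplotypePanel", function(x) x@samples)

#' @describeIn HaplotypePanel phased haplotype matrix (2n x sites).
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' Site coordinates of a panel as a GRanges
#'
#' @param x a [HaplotypePanel-class].
#' @return a `GRanges` with one range per site and `ref`/`alt` metadata
#'   columns.
#' @export
siteRanges <- function(x) {
  stopifnot(is(x, "HaplotypePanel"))
  GenomicRanges::GRanges(x@chrom, IRanges::IRanges(x@pos, x@pos),
                         ref = x@ref, alt = x@alt)
}

#' Alternate-allele dosage matrix of a panel
#'
#' Sums the two phased haplotypes per sample; entries masked as missing at
#' the diploid level are returned as `NA`.
#'
#' @param x a [HaplotypePanel-class].
#' @return numeric samples x sites matrix with entries in \{0,1,2\} or `NA`.
#' @export
dosageMatrix <- function(x) {
  stopifnot(is(x, "HaplotypePanel"))
  H <- x@haplotypes
  d <- H[seq(1, nrow(H), by = 2), , drop = FALSE] +
       H[seq(2, nrow(H), by = 2), , drop = FALSE]
  d[x@missing] <- NA_real_
  rownames(d) <- x@samples
  d
}

#' Observed alternate-allele frequency per site
#'
#' @param x a [HaplotypePanel-class].
#' @param samples optional subset of sample ids.
#' @return per-site frequency computed on non-missing genotypes.
#' @export
alleleFreq <- function(x, samples = NULL) {
  d <- dosageMatrix(x)
  if (!is.null(samples)) d <- d[match(samples, x@samples), , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Subset a panel by samples and/or sites
#'
#' @param x a `HaplotypePanel`.
#' @param i sample index (numeric/logical/character ids).
#' @param j site index.
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@samples)
  if (missing(j)) j <- seq_along(x@pos)
  if (is.character(i)) i <- match(i, x@samples)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  hapRows <- as.vector(rbind(2L * i - 1L, 2L * i))
  HaplotypePanel(x@chrom[j], x@pos[j], x@ref[j], x@alt[j],
                 x@haplotypes[hapRows, j, drop = FALSE], x@samples[i],
                 x@missing[i, j, drop = FALSE], x@metadata)
})

#' Result of a (partial) redundancy analysis
#'
#' @slot eigenvalues canonical eigenvalues per constrained axis.
#' @slot proportions fraction of constrained variance per axis (sums to 1).
#' @slot siteScores sample scores on the canonical axes (linear-combination
#'   scores, i.e. projections of the fitted values).
#' @slot loadings SNP loadings: correlation between each residualized SNP
#'   dosage and each axis's site scores.
#' @slot biplot correlations of the (residualized) predictors with the axes.
#' @slot r2 proportion of (conditioned) genotypic variance explained.
#' @slot adjR2 Ezekiel-adjusted R-squared (NA when n is too small).
#' @slot pseudoF permutation-test pseudo-F statistic.
#' @slot permP permutation p-value with add-one correction.
#' @slot nPermutations number of row permutations used.
#' @slot rank rank of the residualized predictor matrix (= number of axes).
#' @slot dropped names of predictor columns dropped for collinearity.
#' @slot details list: sample size, predictor and conditioning counts.
#' @exportClass RdaResult
setClass("RdaResult", representation(
  eigenvalues = "numeric", proportions = "numeric",
  siteScores = "matrix", loadings = "matrix", biplot = "matrix",
  r2 = "numeric", adjR2 = "numeric", pseudoF = "numeric", permP = "numeric",
  nPermutations = "integer", rank = "integer", dropped = "character",
  details = "list"
))

setValidity("RdaResult", function(object) {
  msg <- character()
  k <- length(object@eigenvalues)
  if (length(object@proportions) != k)
    msg <- c(msg, "one variance proportion per eigenvalue required")
  if (k && abs(sum(object@proportions) - 1) > 1e-8)
    msg <- c(msg, "axis proportions must sum to 1")
  if (!is.na(object@adjR2) && object@adjR2 > object@r2 + 1e-12)
    msg <- c(msg, "adjusted R2 cannot exceed R2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RdaResult", function(object) {
  cat("RdaResult:", object@rank, "constrained axes,",
      nrow(object@loadings), "SNPs\n")
  cat("  R2 =", signif(object@r2, 4), " adj.R2 =", signif(object@adjR2, 4),
      "\n")
  cat("  axis proportions:",
      paste(signif(object@proportions, 3), collapse = " "), "\n")
  cat("  pseudo-F =", signif(object@pseudoF, 4), " perm. p =",
      signif(object@permP, 4), sprintf("(%d permutations)\n",
                                       object@nPermutations))
  if (length(object@dropped))
    cat("  dropped collinear:", paste(object@dropped, collapse = ", "), "\n")
})
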