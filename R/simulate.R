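## Synthetic structured-population generator: metadata, haplotypes, ground
## truth. All functions are deterministic given the seed carried by the
## SimConfig (or an explicit seed argument) and restore the caller's RNG
## state on exit.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.envPredictorNames <- function() {
  c("precip_warmest_q", "precip_coldest_q", "srad_may",
    "elevation_pred", "soil_clay", "temp_seasonality")
}

.traitNames <- function() {
  c("body_weight", "beak_length", "comb_width", "wattle_width",
    "earlobe_width")
}

## Default target correlation matrix among the six environmental predictors
## (order of .envPredictorNames()). Encodes the usual covariation of tropical
## highland climates: precipitation tracks elevation positively, seasonality
## and radiation negatively; modest correlation among the two precipitation
## predictors.
.defaultEnvCor <- function() {
  nm <- .envPredictorNames()
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  set <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set("precip_warmest_q", "elevation_pred", 0.5)
  set("precip_coldest_q", "elevation_pred", 0.3)
  set("precip_warmest_q", "precip_coldest_q", 0.4)
  set("srad_may", "elevation_pred", -0.3)
  set("temp_seasonality", "elevation_pred", -0.4)
  set("srad_may", "temp_seasonality", 0.3)
  set("soil_clay", "precip_warmest_q", 0.2)
  R
}

## Realistic location/scale for each predictor when mapping latent z-scores
## to measurement units (mm, kJ m-2 day-1, %, m, degC*100 sd).
.envScales <- function() {
  data.frame(
    row.names = .envPredictorNames(),
    mean = c(450, 60, 21000, 0, 35, 120),
    sd = c(150, 40, 1500, 1, 10, 30))
}

#' Simulate sample metadata for a gradient-by-agroecology design
#'
#' Lays out `nGradients x agroecologies x popsPerCell` village populations,
#' draws one elevation per population inside its agroecology's band, places
#' populations geographically along their gradient, and generates six
#' environmental predictors as population-level constants whose target
#' correlation structure (including their correlation with elevation) is
#' given by `envCor`. Every sample inherits its population's values: the
#' design records one coordinate and one environmental profile per village.
#'
#' @param config a [SimConfig-class].
#' @param envCor 6x6 target correlation matrix of the environmental
#'   predictors, rows/columns ordered as in the output; must be positive
#'   semi-definite. The `elevation_pred` row fixes how strongly the other
#'   predictors track elevation, and the elevation predictor itself equals
#'   the village elevation.
#' @return a `data.frame` with one row per sample: `sample_id`,
#'   `population_id`, `gradient`, `agroecology`, `longitude`, `latitude`,
#'   `elevation`, the six predictor columns, and five trait columns
#'   (`NA` until [simulateTraits()] fills them). Attributes
#'   `envPredictors` and `traits` name the respective column sets.
#' @examples
#' frame <- simulateMetadata(simConfig(seed = 7L))
#' table(frame$gradient, frame$agroecology)
#' @export
simulateMetadata <- function(config, envCor = .defaultEnvCor()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  envCor <- as.matrix(envCor)
  if (!isSymmetric(unname(envCor)) ||
      min(eigen(envCor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("envCor must be a symmetric positive semi-definite correlation matrix")
  if (nrow(envCor) != 6L)
    stop("envCor must be 6 x 6 (one row per environmental predictor)")

  bands <- .agroBands()
  agro <- config@agroecologies
  gradients <- as.roman(seq_len(config@nGradients))
  cells <- expand.grid(gradient = as.character(gradients), agroecology = agro,
                       stringsAsFactors = FALSE)
  pops <- cells[rep(seq_len(nrow(cells)), each = config@popsPerCell), ]
  nPop <- nrow(pops)
  pops$population_id <- sprintf("pop%02d", seq_len(nPop))

  .withSeed(config@seed, {
    ## elevation inside the agroecology band
    lo <- vapply(pops$agroecology, function(a) bands[[a]][1], numeric(1))
    hi <- vapply(pops$agroecology, function(a) bands[[a]][2], numeric(1))
    pops$elevation <- round(runif(nPop, lo, hi))

    ## geography: gradients occupy separated sectors; villages jitter
    gidx <- match(pops$gradient, as.character(gradients))
    centerLon <- 34 + 2.5 * (gidx - 1)
    centerLat <- 5 + 2.5 * (gidx - 1)
    pops$longitude <- round(centerLon + runif(nPop, -1, 1), 4)
    pops$latitude <- round(centerLat + runif(nPop, -1, 1), 4)

    ## environmental predictors: conditional MVN given the elevation z-score
    ## so the predictor-predictor correlation targets envCor while the
    ## elevation predictor is the village elevation itself
    zElev <- as.numeric(scale(pops$elevation))
    nm <- .envPredictorNames()
    eIdx <- match("elevation_pred", nm)
    So <- envCor[-eIdx, -eIdx, drop = FALSE]
    se <- envCor[-eIdx, eIdx]
    condMean <- outer(zElev, se)                  # nPop x 5
    condCov <- So - tcrossprod(se)                # Schur complement
    ev <- eigen(condCov, symmetric = TRUE)
    rot <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(condCov))
    zOther <- condMean + matrix(rnorm(nPop * (length(nm) - 1L)),
                                nPop) %*% t(rot)
    z <- matrix(NA_real_, nPop, length(nm), dimnames = list(NULL, nm))
    z[, eIdx] <- zElev
    z[, -eIdx] <- zOther
    sc <- .envScales()
    env <- sweep(sweep(z, 2, sc$sd, "*"), 2, sc$mean, "+")
    env[, eIdx] <- pops$elevation                 # natural units
    pops[nm] <- round(env, 3)
  })

  frame <- pops[rep(seq_len(nPop), each = config@samplesPerPop), ]
  frame$sample_id <- sprintf("%s_s%02d", frame$population_id,
                             sequence(rep(config@samplesPerPop, nPop)))
  frame[.traitNames()] <- NA_real_
  rownames(frame) <- NULL
  frame <- frame[c("sample_id", "population_id", "gradient", "agroecology",
                   "longitude", "latitude", "elevation",
                   .envPredictorNames(), .traitNames())]
  attr(frame, "envPredictors") <- .envPredictorNames()
  attr(frame, "traits") <- .traitNames()
  frame
}

## Per-population Balding-Nichols frequency draw around ancestral p with
## differentiation parameter F; F = 0 collapses to p exactly.
.baldingNichols <- function(p, fst) {
  if (fst == 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  rbeta(length(p), a, b)
}

## Resample one population's haplotype block to hit target ALT counts with
## minimal flips: current carriers keep the allele whenever possible, so
## local LD from the founder mosaic survives the frequency adjustment.
.resampleToCounts <- function(hapBlock, counts) {
  H <- nrow(hapBlock)
  m <- ncol(hapBlock)
  key <- hapBlock + runif(H * m)      # ALT entries rank above all REF entries
  ord <- order(col(key), -key)
  pick <- ord[sequence(counts, from = (seq_len(m) - 1L) * H + 1L)]
  out <- matrix(0L, H, m)
  out[pick] <- 1L
  out
}

#' Simulate phased haplotypes under founder-mosaic + Balding-Nichols
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95); each
#' population's target frequencies follow the Balding-Nichols model with
#' parameter `fstLevel`. Haplotypes are built as recombinant mosaics of
#' `founderHaplotypes` templates (switch probability `recombRate` per bp),
#' which creates realistic linkage disequilibrium, then minimally resampled
#' within each population so the ALT count at every site is a Binomial draw
#' at that population's target frequency — yielding both site-level
#' differentiation and haplotype structure.
#'
#' @param config a [SimConfig-class] (its `seed` drives all randomness).
#' @param frame metadata from [simulateMetadata()].
#' @param freqResample resample each population's site counts to its
#'   Balding-Nichols target frequencies (default). With `FALSE` the raw
#'   founder mosaics are returned (no population differentiation beyond
#'   drift in the mosaic draw); useful for studying the LD backbone alone.
#' @return a [HaplotypePanel-class] whose `metadata` carries the ground
#'   truth: `ancestralFreq`, `popFreq` (populations x sites target
#'   frequencies), `populations`, and empty `sweeps`/`clines` registries.
#' @export
simulateHaplotypes <- function(config, frame, freqResample = TRUE) {
  stopifnot(is(config, "SimConfig"), is.data.frame(frame))
  popIds <- unique(frame$population_id)
  samples <- frame$sample_id
  n <- length(samples)
  H <- 2L * n
  m <- config@nSnps
  K <- config@founderHaplotypes

  perChrom <- diff(round(seq(0, m, length.out = config@nChromosomes + 1L)))
  chrom <- rep(sprintf("chr%d", seq_len(config@nChromosomes)), perChrom)

  .withSeed(config@seed + 1L, {
    pos <- unlist(lapply(perChrom, function(k)
      sort(sample.int(config@chromLength, k))), use.names = FALSE)
    pAnc <- runif(m, 0.05, 0.95)
    popFreq <- t(vapply(popIds, function(p)
      .baldingNichols(pAnc, config@fstLevel), numeric(m)))
    rownames(popFreq) <- popIds

    founders <- matrix(rbinom(K * m, 1L, rep(pAnc, each = K)), K, m)

    ## founder-mosaic paths, chromosome by chromosome
    hap <- matrix(0L, H, m)
    off <- 0L
    for (cc in seq_len(config@nChromosomes)) {
      idx <- off + seq_len(perChrom[cc])
      gaps <- diff(pos[idx])
      pSwitch <- 1 - (1 - config@recombRate)^gaps
      f <- sample.int(K, H, replace = TRUE)
      hap[, idx[1L]] <- founders[cbind(f, idx[1L])]
      for (j in seq_along(gaps)) {
        sw <- runif(H) < pSwitch[j]
        if (any(sw)) f[sw] <- sample.int(K, sum(sw), replace = TRUE)
        hap[, idx[j + 1L]] <- founders[cbind(f, idx[j + 1L])]
      }
      off <- off + perChrom[cc]
    }

    ## per-population frequency resampling (binomial target counts)
    if (freqResample) for (p in popIds) {
      rows <- which(rep(frame$population_id, each = 2L) == p)
      counts <- rbinom(m, length(rows), popFreq[p, ])
      hap[rows, ] <- .resampleToCounts(hap[rows, , drop = FALSE], counts)
    }

    missing <- matrix(FALSE, n, m)
    if (config@missingRate > 0)
      missing <- matrix(runif(n * m) < config@missingRate, n, m)

    HaplotypePanel(chrom, pos, rep("A", m), rep("G", m), hap, samples,
                   missing,
                   metadata = list(ancestralFreq = pAnc, popFreq = popFreq,
                                   populations = frame$population_id,
                                   chromLength = config@chromLength,
                                   sweeps = list(), clines = list()))
  })
}

#' Parametric FST from true subpopulation allele frequencies
#'
#' Computes `(HT - HS) / HT`, where `HS` is the weighted mean within-deme
#' expected heterozygosity `2 p (1 - p)` and `HT` the expected
#' heterozygosity at the weighted mean frequency. Returns 0 for identical
#' frequencies and 1 for demes fixed for different alleles; sites that are
#' monomorphic overall (`HT = 0`) are undefined and returned as `NA`.
#'
#' @param freq numeric vector of per-deme frequencies at one site, or a
#'   demes x sites matrix.
#' @param weights per-deme weights (default equal); normalized internally.
#' @return a scalar (vector input) or per-site vector (matrix input).
#' @examples
#' parametricFst(c(0.2, 0.8))  # 0.36
#' @export
parametricFst <- function(freq, weights = NULL) {
  if (is.null(dim(freq))) freq <- matrix(freq, ncol = 1L)
  stopifnot(all(freq >= 0 & freq <= 1, na.rm = TRUE))
  if (is.null(weights)) weights <- rep(1, nrow(freq))
  stopifnot(length(weights) == nrow(freq), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  hs <- colSums(w * 2 * freq * (1 - freq))
  pbar <- colSums(w * freq)
  ht <- 2 * pbar * (1 - pbar)
  out <- ifelse(ht == 0, NA_real_, (ht - hs) / ht)
  if (length(out) == 1L) out <- unname(out)
  out
}
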