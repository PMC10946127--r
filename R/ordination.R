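## Constrained and unconstrained ordination of genotype dosages: genotype
## PCA (Patterson normalization), predictor reduction, partial redundancy
## analysis conditioned on geography, loading-outlier detection and
## candidate-SNP assignment.

#' Genotype PCA with Patterson normalization
#'
#' Mean-imputes missing dosages, centers each SNP and scales it by
#' `sqrt(p(1-p))` with `p` the sample allele frequency, then
#' eigendecomposes the sample covariance `X X' / m`. Monomorphic SNPs are
#' dropped (their count is reported as an attribute).
#'
#' @param dosages samples x SNPs dosage matrix (NA = missing), or a
#'   [HaplotypePanel-class].
#' @param k number of axes to return.
#' @return list with `scores` (n x k projections, `X V / sqrt(m)`),
#'   `eigenvalues` (length k) and attribute `nMonomorphic`.
#' @export
pcaGenotypes <- function(dosages, k = 10L) {
  if (is(dosages, "HaplotypePanel")) dosages <- dosageMatrix(dosages)
  D <- as.matrix(dosages)
  stopifnot(nrow(D) >= 2L, ncol(D) >= 1L)
  mu <- colMeans(D, na.rm = TRUE)
  idx <- which(is.na(D))
  if (length(idx)) D[idx] <- mu[(idx - 1L) %/% nrow(D) + 1L]
  p <- mu / 2
  poly <- p > 0 & p < 1
  nMono <- sum(!poly)
  if (!any(poly)) stop("all SNPs are monomorphic")
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(sweep(D, 2L, 2 * p, "-"), 2L, sqrt(p * (1 - p)), "/")
  m <- ncol(X)
  sv <- svd(X, nu = 0, nv = 0)
  k <- min(k, length(sv$d), nrow(X) - 1L)
  sv <- svd(X, nu = k, nv = k)
  eig <- sv$d[seq_len(k)]^2 / m
  scores <- X %*% sv$v[, seq_len(k), drop = FALSE] / sqrt(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dosages)
  structure(list(scores = scores, eigenvalues = eig),
            nMonomorphic = nMono)
}

#' Greedy reduction of correlated predictors
#'
#' While any predictor pair exceeds the absolute-correlation threshold,
#' the worst offending pair loses the member with the larger mean absolute
#' correlation against all other predictors. Predictors in `forcedKeep`
#' are never dropped; if two forced predictors exceed the threshold they
#' are both retained with a warning (the convention used when a trait pair
#' is deliberately kept for its biological relevance).
#'
#' @param table data.frame or matrix of candidate predictors (columns).
#' @param threshold absolute-correlation threshold; pairs with
#'   `|r| > threshold` (strict) are reduced.
#' @param forcedKeep column names never to drop.
#' @return character vector of retained column names, with attribute
#'   `dropped`.
#' @export
reducePredictors <- function(table, threshold = 0.7,
                             forcedKeep = character()) {
  X <- as.matrix(table)
  stopifnot(ncol(X) >= 2L, threshold > 0)
  keep <- colnames(X)
  dropped <- character()
  repeat {
    R <- abs(cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    droppable <- !(keep %in% forcedKeep)
    cand <- which(R > threshold, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand)) {
      fixable <- droppable[cand[, 1L]] | droppable[cand[, 2L]]
      if (!any(fixable)) {
        warning("forcedKeep retains predictor pair(s) above the threshold: ",
                paste(unique(apply(cand, 1L, function(ij)
                  paste(keep[ij], collapse = "/"))), collapse = ", "))
        break
      }
      cand <- cand[fixable, , drop = FALSE]
    } else break
    worst <- cand[which.max(R[cand]), ]
    pair <- keep[worst]
    pairDroppable <- pair[!(pair %in% forcedKeep)]
    if (length(pairDroppable) == 1L) victim <- pairDroppable
    else {
      meanAbs <- rowMeans(R[pair, , drop = FALSE])
      ## tie: later column order loses
      victim <- pair[order(-meanAbs, -match(pair, keep))][1L]
    }
    dropped <- c(dropped, victim)
    keep <- setdiff(keep, victim)
    if (length(keep) < 2L) break
  }
  structure(keep, dropped = dropped)
}

## Least-squares residuals of each column of M on [intercept, Z].
.residualize <- function(M, qz) qr.resid(qz, M)

#' Partial redundancy analysis of genotype dosages
#'
#' Constrained ordination of a (centered, mean-imputed) dosage matrix on a
#' predictor table, after residualizing both response and predictors on
#' the conditioning covariates (plus intercept). Canonical axes come from
#' the singular-value decomposition of the fitted-value matrix; eigenvalue
#' k is the squared singular value over (n - 1). Adjusted R-squared uses
#' Ezekiel's formula with the conditioning degrees of freedom removed, and
#' significance is assessed by permuting rows of the residualized
#' predictors (pseudo-F, add-one p-value).
#'
#' @param Y samples x SNPs dosage matrix (NA allowed; mean-imputed), or a
#'   [HaplotypePanel-class].
#' @param X predictor data.frame/matrix (samples x p).
#' @param Z conditioning data.frame/matrix (e.g. longitude and latitude),
#'   or NULL for plain RDA.
#' @param permutations number of row permutations (default 999).
#' @param seed seed for the permutation schedule.
#' @param scaleY also standardize SNP columns (default FALSE: centered
#'   allele counts, the ordination convention for dosage data).
#' @return an [RdaResult-class]. Collinear predictor columns (after
#'   residualization) are dropped and recorded in `@dropped`. The
#'   residualized response and predictors are kept in
#'   `@details$Yres` / `@details$Xres` for downstream assignment.
#' @export
partialRda <- function(Y, X, Z = NULL, permutations = 999L, seed = 1L,
                       scaleY = FALSE) {
  if (is(Y, "HaplotypePanel")) Y <- dosageMatrix(Y)
  Y <- as.matrix(Y)
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (!is.null(Z)) {
    Z <- as.matrix(as.data.frame(Z))
    storage.mode(Z) <- "double"
    stopifnot(nrow(Z) == n)
    if (ncol(Z) == 0L) Z <- NULL
  }
  q <- if (is.null(Z)) 0L else ncol(Z)

  ## mean-impute and center the response
  mu <- colMeans(Y, na.rm = TRUE)
  idx <- which(is.na(Y))
  if (length(idx)) Y[idx] <- mu[(idx - 1L) %/% n + 1L]
  Y <- scale(Y, center = TRUE, scale = scaleY)
  Y[is.nan(Y)] <- 0

  qz <- qr(cbind(rep(1, n), Z))
  Yres <- .residualize(Y, qz)
  Xres <- .residualize(X, qz)

  qx <- qr(Xres)
  p <- qx$rank
  if (p == 0L) stop("predictors are fully collinear with the conditioning set")
  used <- qx$pivot[seq_len(p)]
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), used)]
  Xuse <- Xres[, used, drop = FALSE]
  Q <- qr.Q(qr(Xuse))

  B <- crossprod(Q, Yres)                     # p x m
  sv <- svd(t(B), nu = 0)                     # SVD of Yhat shares d, V
  d <- sv$d[seq_len(p)]
  eig <- d^2 / (n - 1)
  axes <- paste0("RDA", seq_len(p))
  siteScores <- (Q %*% sv$v[, seq_len(p), drop = FALSE]) %*% diag(d, p)
  colnames(siteScores) <- axes
  rownames(siteScores) <- rownames(Y)

  ssTot <- sum(Yres^2)
  ssFit <- sum(d^2)
  r2 <- ssFit / ssTot
  adjR2 <- if (n - 1 - q - p > 0)
    1 - (1 - r2) * (n - 1 - q) / (n - 1 - q - p) else NA_real_

  loadings <- suppressWarnings(cor(Yres, siteScores))
  rownames(loadings) <- colnames(Y)
  biplot <- suppressWarnings(cor(Xuse, siteScores))

  fStat <- function(R2) (R2 / p) / ((1 - R2) / (n - 1 - p - q))
  fObs <- fStat(r2)
  permP <- NA_real_
  if (permutations > 0L) {
    ## permute rows of the residualized predictors, then re-residualize on
    ## the conditioning space so each permuted model is a valid partial fit
    fPerm <- .withSeed(seed, vapply(seq_len(permutations), function(b) {
      pr <- sample.int(n)
      Xp <- .residualize(Xuse[pr, , drop = FALSE], qz)
      Qp <- qr.Q(qr(Xp))
      ssb <- sum(crossprod(Qp, Yres)^2)
      fStat(ssb / ssTot)
    }, numeric(1)))
    permP <- (1 + sum(fPerm >= fObs)) / (1 + permutations)
  }

  new("RdaResult", eigenvalues = setNames(eig, axes),
      proportions = setNames(eig / sum(eig), axes),
      siteScores = siteScores, loadings = loadings, biplot = biplot,
      r2 = r2, adjR2 = adjR2, pseudoF = fObs, permP = permP,
      nPermutations = as.integer(permutations), rank = as.integer(p),
      dropped = dropped,
      details = list(n = n, p = p, q = q, Yres = Yres, Xres = Xuse,
                     seed = as.integer(seed)))
}

#' Loading-outlier SNPs from an RDA
#'
#' On each of the first `nAxes` canonical axes, flags SNPs whose loading
#' deviates from the axis mean by more than `sdMult` standard deviations
#' (the 3.5-SD default corresponds to a two-tailed normal p of about
#' 0.0005). The outlier set is the union over axes; each SNP is reported
#' once, on its most extreme axis.
#'
#' @param result an [RdaResult-class].
#' @param sdMult standard-deviation multiplier (default 3.5).
#' @param nAxes number of leading axes inspected (default 3).
#' @return data.frame `(snp, axis, loading, z)` ordered by SNP index;
#'   empty when no axis has positive loading spread.
#' @export
rdaOutliers <- function(result, sdMult = 3.5, nAxes = 3L) {
  stopifnot(is(result, "RdaResult"))
  L <- result@loadings
  nAxes <- min(nAxes, ncol(L))
  Z <- matrix(NA_real_, nrow(L), nAxes)
  for (k in seq_len(nAxes)) {
    lk <- L[, k]
    s <- sd(lk, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    Z[, k] <- (lk - mean(lk, na.rm = TRUE)) / s
  }
  hit <- which(rowSums(abs(Z) > sdMult, na.rm = TRUE) > 0)
  if (!length(hit))
    return(data.frame(snp = integer(), axis = integer(),
                      loading = numeric(), z = numeric()))
  bestAxis <- apply(abs(Z[hit, , drop = FALSE]), 1L, which.max)
  data.frame(snp = hit, axis = bestAxis,
             loading = L[cbind(hit, bestAxis)],
             z = Z[cbind(hit, bestAxis)])
}

.corBins <- function() c(0, 0.3, 0.4, 0.5, 0.6, 1)

#' Assign outlier SNPs to their most correlated predictor
#'
#' For each outlier SNP, computes the Pearson correlation between its
#' residualized dosage and each residualized predictor, assigns the
#' predictor with the largest `|r|` (ties resolved by predictor column
#' order), and bins `|r|` into (0,0.3], (0.3,0.4], (0.4,0.5], (0.5,0.6],
#' (0.6,1]. SNPs whose residualized dosage has zero variance are reported
#' unassigned.
#'
#' @param outliers data.frame from [rdaOutliers()].
#' @param Yres residualized dosage matrix (e.g. `result@details$Yres`).
#' @param Xres residualized predictors (e.g. `result@details$Xres`).
#' @return `outliers` with `predictor`, `r` and `bin` columns appended.
#' @export
assignOutliers <- function(outliers, Yres, Xres) {
  preds <- colnames(Xres)
  out <- outliers
  out$predictor <- rep(NA_character_, nrow(outliers))
  out$r <- rep(NA_real_, nrow(outliers))
  out$bin <- rep(NA_character_, nrow(outliers))
  if (!nrow(outliers)) return(out)
  for (i in seq_len(nrow(outliers))) {
    y <- Yres[, outliers$snp[i]]
    if (sd(y) == 0) next
    r <- as.numeric(cor(y, Xres))
    j <- which.max(abs(r) - 1e-15 * (seq_along(r) - 1))  # tie: first column
    out$predictor[i] <- preds[j]
    out$r[i] <- r[j]
    out$bin[i] <- as.character(cut(abs(r[j]), .corBins()))
  }
  out
}

#' Genotype-environment / genotype-phenotype association pipeline
#'
#' Composes the constrained-ordination association analysis: predictor
#' reduction at `|r| > threshold`, partial RDA conditioned on geography,
#' loading-outlier detection on the leading axes, assignment of each
#' outlier SNP to its most correlated predictor, and a Manhattan-ready
#' per-SNP significance table (`-log10` of the two-tailed normal tail
#' probability of the most extreme standardized loading; the `sdMult`-SD
#' rule corresponds to p = 0.0005 at the default 3.5).
#'
#' @param panel a [HaplotypePanel-class]; LD pruning beforehand (e.g.
#'   [prunePanel()]) is recommended and its absence triggers a warning.
#' @param frame sample metadata with predictor/trait columns.
#' @param mode `"environment"` (environmental predictors) or
#'   `"phenotype"` (quantitative traits).
#' @param condition geography columns used as conditioning set.
#' @param threshold,forcedKeep forwarded to [reducePredictors()]; in
#'   phenotype mode `forcedKeep` defaults to the comb/wattle trait pair.
#' @param sdMult,nAxes forwarded to [rdaOutliers()].
#' @param permutations,seed forwarded to [partialRda()].
#' @return list: `rda` ([RdaResult-class]), `outliers` (assigned outlier
#'   table), `manhattan` (`chrom`, `pos`, `snp`, `z`, `log10p`,
#'   `significant`), `predictors` (retained set), `mode`,
#'   `droppedSamples`.
#' @export
geaPipeline <- function(panel, frame,
                        mode = c("environment", "phenotype"),
                        condition = c("longitude", "latitude"),
                        threshold = 0.7, forcedKeep = NULL,
                        sdMult = 3.5, nAxes = 3L,
                        permutations = 999L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "HaplotypePanel"))
  if (!isTRUE(panel@metadata$ldPruned))
    warning("panel is not marked LD-pruned; consider prunePanel() first")
  vars <- if (mode == "environment") {
    v <- attr(frame, "envPredictors")
    if (is.null(v)) .envPredictorNames() else v
  } else {
    v <- attr(frame, "traits")
    if (is.null(v)) .traitNames() else v
  }
  if (is.null(forcedKeep))
    forcedKeep <- if (mode == "phenotype")
      intersect(c("comb_width", "wattle_width"), vars) else character()

  droppedSamples <- character()
  if (mode == "phenotype") {
    ok <- complete.cases(frame[vars])
    if (!all(ok)) {
      droppedSamples <- frame$sample_id[!ok]
      frame <- frame[ok, , drop = FALSE]
      panel <- panel[frame$sample_id, ]
      message(length(droppedSamples), " sample(s) dropped for missing traits")
    }
  }

  retained <- reducePredictors(frame[vars], threshold, forcedKeep)
  res <- partialRda(panel, frame[retained], frame[condition],
                    permutations = permutations, seed = seed)
  out <- rdaOutliers(res, sdMult = sdMult, nAxes = nAxes)
  out <- assignOutliers(out, res@details$Yres, res@details$Xres)

  L <- res@loadings
  nA <- min(nAxes, ncol(L))
  Z <- vapply(seq_len(nA), function(k) {
    s <- sd(L[, k], na.rm = TRUE)
    if (is.na(s) || s == 0) rep(NA_real_, nrow(L))
    else (L[, k] - mean(L[, k], na.rm = TRUE)) / s
  }, numeric(nrow(L)))
  zMax <- apply(abs(Z), 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  manhattan <- data.frame(chrom = panel@chrom, pos = panel@pos,
                          snp = seq_len(nSites(panel)), z = zMax,
                          log10p = -log10(2 * pnorm(-zMax)),
                          significant = !is.na(zMax) & zMax > sdMult)
  list(rda = res, outliers = out, manhattan = manhattan,
       predictors = as.character(retained), mode = mode,
       droppedSamples = droppedSamples)
}
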