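# Independent reference implementations used as oracles. These are kept
# deliberately naive (enumeration, dense linear algebra) and separate from
# the package's code paths.

# Weir-Cockerham (1984) two-population theta, scalar transcription of the
# published variance-component formulas.
oracleWcTheta <- function(c1, c2, components = FALSE) {
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- (2 * c1[3] + c1[2]) / (2 * n1)
  p2 <- (2 * c2[3] + c2[2]) / (2 * n2)
  h1 <- c1[2] / n1; h2 <- c2[2] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
        ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (components) return(c(a = a, b = b, c = cc))
  if (a + b + cc == 0) NA_real_ else a / (a + b + cc)
}

# HWE exact p by exhaustive enumeration of all orderings of the 2n-allele
# multiset paired into consecutive genotypes (feasible for n <= 4).
oracleHwePermutation <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  stopifnot(n <= 4)
  alleles <- c(rep(0L, 2 * nAA + nAB), rep(1L, nAB + 2 * nBB))
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  pm <- perms(alleles)
  hets <- apply(pm, 1L, function(row) {
    g <- matrix(row, ncol = 2L, byrow = TRUE)
    sum(g[, 1L] != g[, 2L])
  })
  tab <- table(hets) / length(hets)
  pObs <- tab[as.character(nAB)]
  sum(tab[tab <= pObs * (1 + 1e-12)])
}

# HWE exact p from the closed-form conditional distribution written with
# plain factorials (valid for n <= 50 before double overflow).
oracleHweFactorial <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * n - nA
  if (min(nA, nB) == 0) return(1)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- sapply(hets, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((nB - h) / 2)) *
      2^h * factorial(nA) * factorial(nB) / factorial(2 * n)
  })
  pObs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

# EHH among carrier haplotypes over an inclusive site range, by direct
# grouping of the substrings.
oracleEhh <- function(hap, carriers, from, to) {
  seg <- hap[carriers, seq(min(from, to), max(from, to)), drop = FALSE]
  key <- apply(seg, 1L, paste, collapse = "")
  nk <- table(key)
  sum(choose(nk, 2)) / choose(length(carriers), 2)
}

# Dense-projection partial RDA: explicit hat matrices and a full
# eigendecomposition, no QR shortcuts.
oracleRda <- function(Y, X, Z = NULL) {
  n <- nrow(Y)
  Y <- scale(Y, scale = FALSE)
  W <- cbind(rep(1, n), if (!is.null(Z)) as.matrix(Z))
  Pz <- diag(n) - W %*% solve(crossprod(W)) %*% t(W)
  Yres <- Pz %*% Y
  Xres <- Pz %*% as.matrix(X)
  Px <- Xres %*% solve(crossprod(Xres)) %*% t(Xres)
  Yhat <- Px %*% Yres
  ee <- eigen(crossprod(Yhat), symmetric = TRUE)
  p <- qr(Xres)$rank
  eig <- ee$values[seq_len(p)] / (n - 1)
  scores <- Yhat %*% ee$vectors[, seq_len(p), drop = FALSE]
  list(eigenvalues = eig, siteScores = scores,
       r2 = sum(Yhat^2) / sum(Yres^2))
}

# Interval intersection by brute-force all-pairs comparison.
oracleOverlapPairs <- function(windows, genes) {
  hits <- matrix(FALSE, nrow(windows), length(genes))
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  gc <- as.character(GenomicRanges::seqnames(genes))
  for (i in seq_len(nrow(windows)))
    for (j in seq_along(genes))
      hits[i, j] <- windows$chrom[i] == gc[j] &&
        windows$start[i] <= ge[j] && gs[j] <= windows$end[i]
  hits
}
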