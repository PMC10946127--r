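test_that("genotype PCA separates duplicated clusters and matches svd", {
  ## two clusters of duplicated samples: PC1 separates them exactly
  set.seed(3)
  a <- rbinom(80, 2, 0.3)
  b <- rbinom(80, 2, 0.7)
  D <- rbind(matrix(rep(a, 5), 5, byrow = TRUE),
             matrix(rep(b, 5), 5, byrow = TRUE))
  pca <- pcaGenotypes(D, k = 3)
  expect_lt(max(abs(diff(pca$scores[1:5, 1]))), 1e-10)
  expect_lt(max(abs(diff(pca$scores[6:10, 1]))), 1e-10)
  expect_gt(abs(pca$scores[1, 1] - pca$scores[6, 1]), 1e-6)

  ## eigenvalues match a direct dense decomposition on a 50 x 200 panel
  set.seed(4)
  D2 <- matrix(rbinom(50 * 200, 2, runif(200, 0.1, 0.9)), 50, 200,
               byrow = TRUE)
  pca2 <- pcaGenotypes(D2, k = 10)
  p <- colMeans(D2) / 2
  poly <- p > 0 & p < 1
  X <- scale(D2[, poly], center = TRUE, scale = FALSE)
  X <- sweep(X, 2, sqrt(p[poly] * (1 - p[poly])), "/")
  ev <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE, only.values = TRUE)
  expect_equal(pca2$eigenvalues, ev$values[1:10], tolerance = 1e-8)

  ## monomorphic columns are dropped and counted
  D3 <- cbind(D2, 0, 2)
  expect_equal(attr(pcaGenotypes(D3, k = 2), "nMonomorphic"),
               attr(pcaGenotypes(D2, k = 2), "nMonomorphic") + 2L)
})

test_that("gradient structure in simulation is recovered on the top PCs", {
  cfg <- simConfig(nGradients = 2L, popsPerCell = 2L, samplesPerPop = 10L,
                   nChromosomes = 1L, chromLength = 4e6, nSnps = 2000L,
                   fstLevel = 0.2, seed = 41L,
                   agroecologies = "lowland")
  frame <- simulateMetadata(cfg)
  panel <- simulateHaplotypes(cfg, frame)
  pca <- pcaGenotypes(panel, k = 2)
  lab <- frame$gradient
  ## mean silhouette of gradient labels on PC1/2 must be positive
  sc <- pca$scores
  dmat <- as.matrix(dist(sc))
  sil <- vapply(seq_len(nrow(sc)), function(i) {
    own <- mean(dmat[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    oth <- mean(dmat[i, lab != lab[i]])
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("predictor reduction enforces the |r| > 0.7 rule", {
  set.seed(6)
  n <- 300
  base <- rnorm(n)
  tab <- data.frame(a = base + rnorm(n, 0, 0.3),     # a,b strongly correlated
                    b = base + rnorm(n, 0, 0.3),
                    c = rnorm(n), d = rnorm(n))
  expect_gt(abs(cor(tab$a, tab$b)), 0.7)
  kept <- reducePredictors(tab, 0.7)
  expect_equal(sum(c("a", "b") %in% kept), 1L)
  expect_true(all(c("c", "d") %in% kept))

  ## all pairwise |r| <= threshold: nothing dropped (strict inequality)
  tab2 <- data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  expect_equal(as.character(reducePredictors(tab2, abs(cor(tab2$x, tab2$y)))),
               c("x", "y"))

  ## forced-keep pair above threshold: both retained, with a warning
  set.seed(7)
  z <- rnorm(n)
  tab3 <- data.frame(comb_width = z + rnorm(n, 0, 0.55),
                     wattle_width = z + rnorm(n, 0, 0.55),
                     other = rnorm(n))
  expect_gt(abs(cor(tab3$comb_width, tab3$wattle_width)), 0.7)
  expect_warning(
    kept3 <- reducePredictors(tab3, 0.7,
                              forcedKeep = c("comb_width", "wattle_width")),
    "forcedKeep")
  expect_true(all(c("comb_width", "wattle_width") %in% kept3))
})

test_that("partial RDA matches the dense projection oracle", {
  set.seed(8)
  n <- 50; m <- 300; p <- 4; q <- 2
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  Z <- matrix(rnorm(n * q), n, dimnames = list(NULL, c("lon", "lat")))
  B <- matrix(rnorm(p * m, 0, 0.2), p, m)
  Y <- X %*% B + matrix(rnorm(n * m), n, m)

  fit <- partialRda(Y, X, Z, permutations = 0L)
  orc <- oracleRda(Y, X, Z)
  expect_equal(unname(fit@eigenvalues), orc$eigenvalues[1:p],
               tolerance = 1e-8)
  expect_equal(fit@r2, orc$r2, tolerance = 1e-10)
  ## site scores agree up to per-axis sign
  for (k in 1:p) {
    d <- min(max(abs(fit@siteScores[, k] - orc$siteScores[, k])),
             max(abs(fit@siteScores[, k] + orc$siteScores[, k])))
    expect_lt(d, 1e-6)
  }
  expect_equal(sum(fit@proportions), 1, tolerance = 1e-10)
  expect_equal(fit@rank, p)

  ## empty conditioning equals plain RDA
  fit0 <- partialRda(Y, X, NULL, permutations = 0L)
  orc0 <- oracleRda(Y, X, NULL)
  expect_equal(unname(fit0@eigenvalues), orc0$eigenvalues[1:p],
               tolerance = 1e-10)
})

test_that("partial RDA agrees with vegan as an independent cross-check", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 40; m <- 60
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  Y <- matrix(rnorm(n * m), n, m)
  Y[, 1:10] <- Y[, 1:10] + outer(X$x1, rep(0.8, 10))

  fit <- partialRda(Y, X, NULL, permutations = 0L)
  vg <- vegan::rda(Y ~ x1 + x2 + x3, data = X)
  expect_equal(unname(fit@eigenvalues),
               unname(vg$CCA$eig), tolerance = 1e-8)
  expect_equal(fit@r2, vg$CCA$tot.chi / vg$tot.chi, tolerance = 1e-10)
  expect_equal(fit@adjR2, vegan::RsquareAdj(vg)$adj.r.squared,
               tolerance = 1e-10)

  ## partial model: conditioned eigenvalues also agree
  Z <- data.frame(lon = rnorm(n), lat = rnorm(n))
  dat <- cbind(X, Z)
  fitP <- partialRda(Y, X, Z, permutations = 0L)
  vgP <- vegan::rda(Y ~ x1 + x2 + x3 + Condition(lon + lat), data = dat)
  expect_equal(unname(fitP@eigenvalues), unname(vgP$CCA$eig),
               tolerance = 1e-8)
})

test_that("perfect linear response gives R2 = 1 and Ezekiel values check", {
  set.seed(10)
  n <- 30
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("x", 1:3)))
  Y <- X %*% matrix(rnorm(3 * 20), 3, 20)
  fit <- partialRda(Y, X, NULL, permutations = 0L)
  expect_equal(fit@r2, 1, tolerance = 1e-10)
  expect_equal(fit@adjR2, 1, tolerance = 1e-10)

  ## Ezekiel adjustment: hand-computed and monotone in p
  adj <- function(r2, n, p, q) 1 - (1 - r2) * (n - 1 - q) / (n - 1 - q - p)
  set.seed(11)
  Y2 <- matrix(rnorm(n * 20), n, 20)
  f2 <- partialRda(Y2, X, NULL, permutations = 0L)
  expect_equal(f2@adjR2, adj(f2@r2, n, 3, 0), tolerance = 1e-12)
  expect_lt(adj(0.3, 50, 6, 0), adj(0.3, 50, 3, 0))

  ## collinear predictor is dropped and reported
  X3 <- cbind(X, x4 = X[, 1] + X[, 2])
  f3 <- partialRda(Y2, X3, NULL, permutations = 0L)
  expect_equal(f3@rank, 3L)
  expect_equal(length(f3@dropped), 1L)
})

test_that("loading outliers follow the 3.5-SD two-tailed rule", {
  mkResult <- function(L) {
    k <- ncol(L)
    new("RdaResult", eigenvalues = rep(1, k), proportions = rep(1 / k, k),
        siteScores = matrix(0, 2, k), loadings = L,
        biplot = matrix(0, 1, k), r2 = 0.5, adjR2 = 0.4, pseudoF = 1,
        permP = NA_real_, nPermutations = 0L, rank = as.integer(k),
        dropped = character(), details = list())
  }
  ## all loadings identical: degenerate SD, no outliers
  expect_equal(nrow(rdaOutliers(mkResult(matrix(0.2, 100, 1)), nAxes = 1)), 0L)

  ## planted 10-SD loadings among Gaussian noise are all recovered
  set.seed(12)
  L <- matrix(rnorm(10000), ncol = 1)
  planted <- sample(10000, 5)
  L[planted] <- 10 * sd(L)
  out <- rdaOutliers(mkResult(L), sdMult = 3.5, nAxes = 1)
  expect_true(all(planted %in% out$snp))
  expect_lte(nrow(out), 5 + qpois(0.999, 10000 * 5e-4))
})

test_that("outlier assignment picks the most correlated predictor and bins", {
  set.seed(13)
  n <- 200
  Xres <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("A", "B")))
  yStrong <- 0.9 * scale(Xres[, "A"]) + rnorm(n, 0, sqrt(1 - 0.81))
  Yres <- cbind(yStrong, rnorm(n))
  out <- data.frame(snp = 1L, axis = 1L, loading = 0.5, z = 4)
  got <- assignOutliers(out, Yres, Xres)
  expect_equal(got$predictor, "A")
  expect_gt(abs(got$r), 0.6)
  expect_equal(got$bin, "(0.6,1]")

  ## boundary convention: |r| exactly 0.3 falls in (0,0.3]
  expect_equal(as.character(cut(0.3, selscape:::.corBins())), "(0,0.3]")

  ## zero-variance dosage stays unassigned
  Y0 <- cbind(rep(0, n), rnorm(n))
  got0 <- assignOutliers(out, Y0, Xres)
  expect_true(is.na(got0$predictor))
})

test_that("gea pipeline is deterministic and reports dropped samples", {
  fx <- tinyFixture()
  frame <- simulateTraits(fx$panel, fx$frame, residualSd = 1, seed = 14L)
  panel <- fx$panel
  panel@metadata$ldPruned <- TRUE
  g1 <- geaPipeline(panel, frame, mode = "environment", permutations = 49L,
                    seed = 2L)
  g2 <- geaPipeline(panel, frame, mode = "environment", permutations = 49L,
                    seed = 2L)
  expect_identical(g1$rda@eigenvalues, g2$rda@eigenvalues)
  expect_identical(g1$outliers, g2$outliers)
  expect_identical(g1$manhattan, g2$manhattan)

  frameNA <- frame
  frameNA$body_weight[1:3] <- NA
  expect_message(
    gP <- geaPipeline(panel, frameNA, mode = "phenotype",
                      permutations = 0L),
    "dropped")
  expect_equal(length(gP$droppedSamples), 3L)
  expect_warning(geaPipeline(fx$panel, frame, mode = "environment",
                             permutations = 0L), "prun")
})
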