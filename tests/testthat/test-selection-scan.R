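test_that("Weir-Cockerham components match the formula oracle", {
  ## complete differentiation
  expect_equal(wcFst(c(10, 0, 0), c(0, 0, 10))$theta, 1)
  ## identical symmetric populations: small negative theta (estimator bias)
  th <- wcFst(c(5, 0, 5), c(5, 0, 5))
  expect_lt(th$theta, 0)
  expect_lt(th$a, 0)
  expect_gt(th$b, 0)
  expect_equal(th$c, 0)
  ## worked contrast vs the independent scalar transcription
  expect_equal(wcFst(c(8, 2, 0), c(1, 4, 5))$theta,
               oracleWcTheta(c(8, 2, 0), c(1, 4, 5)), tolerance = 1e-12)
  ## random counts: components and theta to 1e-12
  set.seed(23)
  for (i in 1:100) {
    c1 <- as.vector(stats::rmultinom(1, sample(5:30, 1), runif(3)))
    c2 <- as.vector(stats::rmultinom(1, sample(5:30, 1), runif(3)))
    got <- wcFst(c1, c2)
    expect_equal(unname(unlist(got[c("a", "b", "c")])),
                 unname(oracleWcTheta(c1, c2, components = TRUE)),
                 tolerance = 1e-12)
    th <- oracleWcTheta(c1, c2)
    if (is.na(th)) expect_true(is.na(got$theta))
    else expect_equal(got$theta, th, tolerance = 1e-12)
    expect_true(is.na(got$theta) || got$theta <= 1)
  }
  ## monomorphic across both populations is undefined
  expect_true(is.na(wcFst(c(10, 0, 0), c(10, 0, 0))$theta))
})

test_that("window tiling follows the 50kb/25kb contract", {
  w <- makeWindows(c(chr1 = 1e5))
  expect_equal(w$start, c(1, 25001, 50001, 75001))
  expect_equal(w$end, c(50000, 75000, 100000, 100000))
  w2 <- makeWindows(c(chr1 = 40000))
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$end, c(40000, 40000))
  expect_error(makeWindows(c(chr1 = 1e5), span = 1000, step = 2000),
               "span")
  ## membership of a position in overlapping windows
  m <- selscape:::.siteWindowMap("chr1", 60000L, w)
  expect_setequal(w$start[m[, "window"]], c(25001, 50001))
})

test_that("windowed FST averages per-site theta within windows", {
  ## single informative SNP in a window: the mean is that SNP's theta
  hap <- matrix(0L, 16L, 3L)
  hap[1:8, 1L] <- 1L                 # fixed difference at site 1
  hap[c(1, 3, 9, 11), 2L] <- 1L      # shared polymorphism at site 2
  panel <- manualPanel(hap, pos = c(10000L, 30000L, 70000L))
  w <- makeWindows(c(chr1 = 80000))
  A <- sprintf("s%02d", 1:4)
  B <- sprintf("s%02d", 5:8)
  ws <- windowedFst(panel, A, B, w)
  ## window [1,50000] holds sites 1-2; site 3 is monomorphic -> NA windows
  thetas <- wcFst(rbind(c(0, 0, 4), c(2, 2, 0)),
                  rbind(c(4, 0, 0), c(2, 2, 0)))$theta
  expect_equal(ws$stat[1], mean(thetas))
  expect_equal(ws$n_snps[1], 2L)
  expect_true(is.na(ws$stat[3]))     # window with only the monomorphic site

  ## identical populations: genome-wide mean near zero
  fx <- tinyFixture()
  frame <- fx$frame
  pop1 <- frame$sample_id[frame$population_id == frame$population_id[1]]
  half <- seq_along(pop1) %% 2 == 0
  wAll <- makeWindows(c(chr1 = 2e6))
  wsNull <- windowedFst(fx$panel, pop1[half], pop1[!half], wAll)
  expect_lt(abs(mean(wsNull$stat, na.rm = TRUE)), 0.05)
})

test_that("EHH is 1 at the core, non-increasing, and matches enumeration", {
  fx <- tinyFixture()
  panel <- fx$panel
  samples <- fx$frame$sample_id[1:10]
  freq <- alleleFreq(panel, samples)
  core <- which(freq > 0.3 & freq < 0.7)[5]
  curve <- ehh(panel, samples, core, allele = 1L)

  vals <- c(curve$left$ehh, curve$right$ehh)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(curve$right$ehh) <= 1e-12))
  expect_true(all(diff(curve$left$ehh) <= 1e-12))

  rows <- selscape:::.hapRows(panel, samples)
  carriers <- rows[panel@haplotypes[rows, core] == 1L]
  for (k in seq_len(min(5L, nrow(curve$right)))) {
    expect_equal(curve$right$ehh[k],
                 oracleEhh(panel@haplotypes, carriers, core,
                           curve$right$site[k]), tolerance = 1e-12)
  }
  for (k in seq_len(min(5L, nrow(curve$left)))) {
    expect_equal(curve$left$ehh[k],
                 oracleEhh(panel@haplotypes, carriers, core,
                           curve$left$site[k]), tolerance = 1e-12)
  }
})

test_that("EHH combinatorics: 2 of 3 carriers identical gives 1/3", {
  hap <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 1, 1, 1),
               c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 1, 1, 0))
  storage.mode(hap) <- "integer"
  panel <- manualPanel(hap)
  curve <- ehh(panel, c("s01", "s02", "s03"), core = 1L, allele = 1L,
               cutoff = 0)
  ## carriers: rows 1,2,3; over sites 1:2 rows 1,2 stay identical
  expect_equal(curve$right$ehh[1], 1 / 3)
  expect_error(ehh(panel, "s01", core = 2L, allele = 1L), "carriers")
})

test_that("sweep at full carrier fraction yields EHH 1 across the span", {
  fx <- tinyFixture()
  pops <- unique(fx$frame$population_id)
  swept <- injectSweep(fx$panel, pops[1], "chr1", 1e6,
                       carrierFraction = 1, span = 6e5, seed = 5L)
  idx <- swept@metadata$sweeps[[1]]$siteRange
  core <- (idx[1] + idx[2]) %/% 2
  samples <- fx$frame$sample_id[fx$frame$population_id == pops[1]]
  al <- swept@haplotypes[selscape:::.hapRows(swept, samples)[1], core]
  curve <- ehh(swept, samples, core, allele = al)
  inSpan <- curve$right$site <= idx[2]
  expect_true(all(curve$right$ehh[inSpan] == 1))
  inSpanL <- curve$left$site >= idx[1]
  expect_true(all(curve$left$ehh[inSpanL] == 1))
})

test_that("iHH integrates the decay curve correctly", {
  mk <- function(leftPos, leftEhh, rightPos, rightEhh, corePos = 0) {
    structure(list(core = 1L, corePos = corePos, allele = 1L,
                   nCarriers = 4L, cutoff = 0.05,
                   left = data.frame(site = seq_along(leftPos),
                                     pos = leftPos, ehh = leftEhh),
                   right = data.frame(site = seq_along(rightPos),
                                      pos = rightPos, ehh = rightEhh)),
              class = "EhhCurve")
  }
  ## EHH identically 1 over +/- L
  expect_equal(ihh(mk(c(-500, -1000), c(1, 1), c(500, 1000), c(1, 1))), 2000)
  ## one-sided trapezoid: {1 at 0, 0.5 at 100} -> 75
  expect_equal(ihh(mk(numeric(), numeric(), 100, 0.5)), 75)
  ## degenerate single-point curve
  expect_equal(ihh(mk(numeric(), numeric(), numeric(), numeric())), 0)
  ## faster decay integrates strictly smaller
  slow <- ihh(mk(numeric(), numeric(), c(100, 200), c(0.9, 0.8)))
  fast <- ihh(mk(numeric(), numeric(), c(100, 200), c(0.6, 0.2)))
  expect_lt(fast, slow)
})

test_that("XP-EHH is zero for identical panels and antisymmetric on swap", {
  fx <- tinyFixture()
  frame <- fx$frame
  pops <- unique(frame$population_id)
  A <- frame$sample_id[frame$population_id == pops[1]]
  B <- frame$sample_id[frame$population_id == pops[2]]

  ## identical haplotype sets: duplicate population A into fresh ids
  idxA <- match(A, fx$panel@samples)
  rowsA <- as.vector(rbind(2L * idxA - 1L, 2L * idxA))
  hap2 <- rbind(fx$panel@haplotypes[rowsA, ], fx$panel@haplotypes[rowsA, ])
  twin <- manualPanel(hap2, pos = fx$panel@pos)
  xpTwin <- xpehh(twin, sprintf("s%02d", 1:10), sprintf("s%02d", 11:20))
  expect_true(all(abs(xpTwin$sites$raw) < 1e-12, na.rm = TRUE))

  xpAB <- xpehh(fx$panel, A, B)
  xpBA <- xpehh(fx$panel, B, A)
  expect_equal(xpAB$sites$raw, -xpBA$sites$raw, tolerance = 1e-12)
  expect_equal(xpAB$sites$std, -xpBA$sites$std, tolerance = 1e-10)
  ## standardization: mean 0, sd 1 over defined scores
  s <- xpAB$sites$std
  expect_lt(abs(mean(s, na.rm = TRUE)), 1e-10)
  expect_equal(sd(s[!is.na(s)]), 1, tolerance = 1e-10)
})

test_that("empirical ranking flags exactly the top fraction", {
  w <- makeWindows(c(chr1 = 100 * 25000))
  w <- w[1:100, ]
  ws <- selscape:::.newWindowStats(w, rep(1L, 100), rep(NA_real_, 100), "fst")
  set.seed(7)
  ws$stat <- sample(seq(0.001, 0.1, length.out = 100))

  out <- empiricalP(ws, twoSided = FALSE)
  top <- which.max(ws$stat)
  expect_equal(out$p[top], 0.01)
  expect_true(out$significant[top])
  second <- order(-ws$stat)[2]
  expect_equal(out$p[second], 0.02)
  expect_false(out$significant[second])
  expect_equal(sum(out$significant), 1L)   # floor(0.01 * 100)

  ## ties share the worst rank: fully tied scan is never significant
  ws$stat <- rep(0.5, 100)
  tied <- empiricalP(ws, twoSided = FALSE)
  expect_true(all(tied$p == 1))
  expect_false(any(tied$significant))

  ## two-sided: flags match the signed -log10 threshold
  set.seed(8)
  ws$stat <- rnorm(100)
  two <- empiricalP(ws, twoSided = TRUE)
  expect_equal(two$significant, abs(two$signed_log10p) >= 2 - 1e-9)
  expect_true(all(sign(two$signed_log10p[two$stat < 0]) == -1))
  expect_true(all(two$p > 0 & two$p <= 1))
  ## p values lie on the rank grid k/N
  expect_true(all(abs(two$p * 100 - round(two$p * 100)) < 1e-9))
})

test_that("overlap reports all three denominators", {
  w <- makeWindows(c(chr1 = 20 * 25000))[1:20, ]
  mk <- function(sig) {
    ws <- selscape:::.newWindowStats(w, rep(1L, 20), rep(NA_real_, 20), "x")
    ws$significant <- seq_len(20) %in% sig
    ws
  }
  ident <- overlapWindows(mk(1:5), mk(1:5))
  expect_equal(c(ident$pctUnion, ident$pctOfA, ident$pctOfB),
               c(100, 100, 100))
  disj <- overlapWindows(mk(1:5), mk(6:10))
  expect_equal(c(disj$pctUnion, disj$pctOfA, disj$pctOfB), c(0, 0, 0))
  ov <- overlapWindows(mk(1:10), mk(6:15))
  expect_equal(ov$nIntersect, 5L)
  expect_equal(c(ov$pctUnion, ov$pctOfA, ov$pctOfB), c(100 / 3, 50, 50))

  w2 <- makeWindows(c(chr2 = 5e5))
  other <- selscape:::.newWindowStats(w2, rep(1L, nrow(w2)),
                                      rep(NA_real_, nrow(w2)), "x")
  expect_error(overlapWindows(mk(1:5), other), "tiling")
})

test_that("analytical layers expand into the right sample contrasts", {
  cfg <- simConfig(nGradients = 4L, popsPerCell = 1L, samplesPerPop = 4L,
                   seed = 21L)
  frame <- simulateMetadata(cfg)

  l1 <- layerContrasts(frame, "I")
  expect_equal(length(l1), choose(4, 2))
  expect_true("I vs III" %in% names(l1))
  sel <- layerContrasts(frame, "I",
                        pairs = list(c("I", "III"), c("I", "IV"),
                                     c("III", "IV")))
  expect_equal(length(sel), 3L)

  l2 <- layerContrasts(frame, "II")
  expect_equal(length(l2), 3L)
  gradOf <- frame$gradient[match(l2[[1]]$samplesA, frame$sample_id)]
  expect_false("II" %in% gradOf)   # pooled layer excludes gradient II

  l3 <- layerContrasts(frame, "III")
  allSamp <- unlist(lapply(l3, function(ct) c(ct$samplesA, ct$samplesB)))
  expect_true(all(frame$gradient[match(allSamp, frame$sample_id)] == "II"))
})

test_that("layered scan is deterministic and summarizes in input order", {
  cfg <- simConfig(nGradients = 2L, popsPerCell = 1L, samplesPerPop = 8L,
                   nChromosomes = 1L, chromLength = 1e6, nSnps = 300L,
                   fstLevel = 0.05, seed = 31L,
                   agroecologies = c("lowland", "highland"))
  frame <- simulateMetadata(cfg)
  panel <- simulateHaplotypes(cfg, frame)
  s1 <- layeredScan(panel, frame, layer = "I")
  s2 <- layeredScan(panel, frame, layer = "I")
  expect_identical(summarizeContrasts(s1), summarizeContrasts(s2))
  tab <- summarizeContrasts(s1)
  expect_equal(tab$contrast, names(s1))
  expect_true(all(c("meanFst", "nSigFst", "nSigXpehh", "pctUnion")
                  %in% names(tab)))
})
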