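# SNP-effect back-solving, weight updates, window partitioning, and the
# iterative scan.

test_that("back-solved effects reproduce GEBVs through unblended G", {
  set.seed(3)
  n <- 40
  m <- 200
  M <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)), n, m, byrow = FALSE)
  rownames(M) <- paste0("i", 1:n)
  # external (non-observed) frequencies keep G nonsingular
  pExt <- pmin(pmax(colMeans(M) / 2 + 0.02, 0.01), 0.99)
  Z <- centerDosages(M, pExt)
  G <- buildG(M, p = pExt)
  gHat <- rnorm(n)
  u <- backsolveSnpEffects(gHat, Z, G)
  expect_lt(max(abs(as.numeric(Z %*% u) - gHat)), 1e-8)
  expect_equal(unname(backsolveSnpEffects(rep(0, n), Z, G)),
               rep(0, m)) # zero GEBVs give zero effects
})

test_that("all-genotyped back-solve equals direct ridge SNP-BLUP", {
  # unrelated animals, LD-free dense panel: G is safely full rank
  cfg <- smallConfig(seed = 41, nFounders = 90L, nGenerations = 1L,
                     nSnpsPerChrom = 400L, ldLengthBp = 0,
                     genotypedFraction = 1.0,
                     qtlWindows = data.frame(chrom = 1L, startBp = 4e6,
                                             endBp = 6e6, fraction = 0.05))
  pop <- simulatePopulation(cfg)
  geno <- qcFilter(pop$geno)$geno
  dat <- pop$pheno
  gids <- animalIds(geno)
  dat <- dat[match(gids, dat$id), ]
  X <- designMatrix(dat[, c("sex", "farm")])
  pExt <- pmin(pmax(alleleFrequencies(geno) + 0.01, 0.01), 0.99)
  Z <- centerDosages(geno, pExt)
  G <- buildG(geno, p = pExt) # nonsingular: n < m, external frequencies
  vc <- list(sigmaA2 = 40, sigmaE2 = 90)
  Kinv <- chol2inv(chol(relMatrix(G)))
  dimnames(Kinv) <- dimnames(relMatrix(G))
  sol <- solveMME(dat$y, X, dat$id, Kinv, vc)
  u <- backsolveSnpEffects(breedingValues(sol)[gids], Z, G)
  uRef <- oracleSnpBlup(dat$y, X, Z, vc$sigmaA2, vc$sigmaE2, G@sum2pq)
  expect_lt(max(abs(unname(u) - uRef)), 1e-6)
})

test_that("weight update follows d = u^2 * 2p(1-p)", {
  expect_equal(updateWeights(0.5, 0.5), 0.125)
  expect_equal(updateWeights(0, 0.3), 0)
  expect_equal(updateWeights(1, 0.1), 0.18)
  expect_error(updateWeights(1, 0), "frequencies")
  expect_error(updateWeights(NaN, 0.5), "finite")
})

test_that("weight normalization conserves the trace", {
  expect_equal(normalizeWeights(c(1, 3)), c(0.5, 1.5))
  d <- runif(50, 0, 2)
  expect_equal(sum(normalizeWeights(d)), 50)
  dSum <- normalizeWeights(runif(50), dOld = d)
  expect_equal(sum(dSum), sum(d))
  already <- c(0.5, 1.5)
  expect_equal(normalizeWeights(already), already) # already normalized
  expect_error(normalizeWeights(c(0, 0)), "zero")
})

test_that("window assignment bins half-open 0.8 Mb intervals per chromosome", {
  map <- data.frame(snp = paste0("s", 1:3), chrom = "1",
                    pos = c(0.1e6, 0.5e6, 0.9e6))
  w <- assignWindows(map)
  expect_equal(w$index, c(1, 1, 2))
  expect_equal(w$windows$nSnps, c(2L, 1L))
  # a SNP exactly on the boundary opens the next window
  wb <- assignWindows(data.frame(snp = "s", chrom = "1", pos = 8e5))
  expect_equal(wb$windows$startBp, 8e5)
  # a 2.0 Mb chromosome yields at most 3 bins
  m3 <- data.frame(snp = paste0("s", 1:20), chrom = "1",
                   pos = seq(1e5, 2e6, length.out = 20))
  expect_lte(nrow(assignWindows(m3)$windows), 3)
  # SNP-free bins are dropped
  gap <- data.frame(snp = c("a", "b"), chrom = "1", pos = c(1e5, 40e5))
  expect_equal(nrow(assignWindows(gap)$windows), 2)
  expect_error(assignWindows(data.frame(snp = "s", chrom = NA, pos = 1)),
               "unmapped")
})

test_that("window variance partition has exact degenerate limits", {
  set.seed(8)
  n <- 30
  m <- 50
  M <- matrix(rbinom(n * m, 2, 0.5), n, m)
  Z <- centerDosages(M)
  u <- rnorm(m)
  # one whole-genome window explains exactly 100%
  oneWin <- assignWindows(data.frame(snp = paste0("s", 1:m), chrom = "1",
                                     pos = seq_len(m) * 1e3))
  wv <- windowVariance(Z, u, oneWin)
  expect_equal(nrow(wv), 1)
  expect_equal(wv$gvarPercent, 100)
  # a window with zero effects explains 0%
  map2 <- data.frame(snp = paste0("s", 1:m), chrom = rep(c("1", "2"),
                                                         each = m / 2),
                     pos = rep(seq_len(m / 2) * 1e3, 2))
  u2 <- c(rnorm(m / 2), rep(0, m / 2))
  wv2 <- windowVariance(Z, u2, assignWindows(map2))
  expect_equal(wv2$gvarPercent[wv2$chrom == "2"], 0)
  # explicit sigmaA2 denominator
  wv3 <- windowVariance(Z, u, oneWin, denominator = "sigmaA2", sigmaA2 = 50)
  popVar <- mean((Z %*% u - mean(Z %*% u))^2)
  expect_equal(wv3$gvarPercent, popVar / 50 * 100)
  expect_error(windowVariance(Z, u, oneWin, denominator = "sigmaA2"),
               "sigmaA2")
})

test_that("region report thresholds strictly, sorts, extends and clips", {
  w <- data.frame(window = 1:3, chrom = c("4", "2", "9"),
                  startBp = c(4.8e6, 1.6e6, 0), endBp = c(5.6e6, 2.4e6, 8e5),
                  nSnps = c(43L, 20L, 5L), gvarPercent = c(2.5, 1.2, 0.9))
  rep <- reportRegions(w, threshold = 1.0, topK = 3, flankBp = 4e5)
  expect_equal(nrow(rep$significant), 2)
  expect_equal(rep$significant$gvarPercent, c(2.5, 1.2)) # descending
  expect_equal(rep$totalGvarPercent, 3.7)
  # top window extended by 0.4 Mb on each side
  expect_equal(rep$topRegions$startBp[1], 4.4e6)
  expect_equal(rep$topRegions$endBp[1], 6.0e6)
  # flank clipped at the chromosome start
  expect_equal(rep$topRegions$startBp[rep$topRegions$chrom == "9"], 0)
  # clipping at a supplied chromosome end
  rep2 <- reportRegions(w, chromLengths = c("4" = 5.8e6, "2" = 1e7,
                                            "9" = 1e7))
  expect_equal(rep2$topRegions$endBp[1], 5.8e6)
  expect_s4_class(rep2$regions, "GRanges")
  # a 1.6 Mb span reported at 4.38-5.98 Mb extends to 3.98-6.38 Mb
  span <- data.frame(window = 1, chrom = "4", startBp = 4.38e6,
                     endBp = 5.98e6, nSnps = 43L, gvarPercent = 3.07)
  rep3 <- reportRegions(span, topK = 1)
  expect_equal(c(rep3$topRegions$startBp, rep3$topRegions$endBp),
               c(3.98e6, 6.38e6))
})

test_that("windows at the genome-average share are never significant", {
  nWin <- 400
  w <- data.frame(window = seq_len(nWin), chrom = "1",
                  startBp = (seq_len(nWin) - 1) * 8e5,
                  endBp = seq_len(nWin) * 8e5, nSnps = 10L,
                  gvarPercent = rep(100 / nWin, nWin))
  rep <- reportRegions(w)
  expect_equal(nrow(rep$significant), 0)
  expect_equal(rep$totalGvarPercent, 0)
})

test_that("the scan loop is deterministic and degenerates to one iteration", {
  cfg <- smallConfig(seed = 77, nFounders = 40L)
  pop <- simulatePopulation(cfg)
  geno <- qcFilter(pop$geno)$geno
  fit1 <- runWssGwas(pop$ped, geno, pop$pheno, fixed = c("sex", "farm"),
                     nIterations = 1L)
  expect_equal(fit1@state@iteration, 1L)
  expect_equal(unname(snpWeights(fit1)),
               unname(normalizeWeights(updateWeights(snpEffects(fit1),
                                                     alleleFrequencies(geno)))))
  fit3a <- runWssGwas(pop$ped, geno, pop$pheno, fixed = c("sex", "farm"))
  fit3b <- runWssGwas(pop$ped, geno, pop$pheno, fixed = c("sex", "farm"))
  expect_identical(snpWeights(fit3a), snpWeights(fit3b))
  expect_identical(windowVariances(fit3a), windowVariances(fit3b))
  # trace conservation after every iteration
  m <- length(snpEffects(fit3a))
  for (h in fit3a@state@history) {
    expect_equal(sum(h$effects$d), m, tolerance = 1e-9)
  }
  # first-iteration scan reuses unweighted G: history[[1]] of the 3-run
  # equals the 1-iteration run
  expect_equal(fit3a@state@history[[1]]$effects$u,
               fit1@state@history[[1]]$effects$u, tolerance = 1e-10)
})
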