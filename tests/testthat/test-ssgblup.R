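# H-inverse assembly, AI-REML variance components, and the MME solver.

# small single-step scene shared across tests
ssScene <- function(seed = 4L, ...) {
  cfg <- smallConfig(seed = seed, ...)
  pop <- simulatePopulation(cfg)
  qc <- qcFilter(pop$geno)
  list(pop = pop, geno = qc$geno, ped = pop$ped, pheno = pop$pheno)
}

test_that("H-inverse reduces to A-inverse when G equals A22", {
  sc <- ssScene()
  ped <- sc$ped
  gids <- animalIds(sc$geno)
  Ainv <- buildAInverse(ped)
  a22 <- subsetA22(ped, gids)
  Hinv <- buildHInverse(Ainv, a22$A22inv, a22$A22inv, gids) # Ginv := A22inv
  expect_lt(max(abs(Hinv - Ainv)), 1e-10)
  # no genotyped animals at all
  expect_identical(buildHInverse(Ainv, NULL, NULL, character()), Ainv)
})

test_that("H from inverting H-inverse is positive definite", {
  sc <- ssScene(seed = 8L, nFounders = 20L)
  gids <- animalIds(sc$geno)
  Ainv <- buildAInverse(sc$ped)
  a22 <- subsetA22(sc$ped, gids)
  G <- blendG(buildG(sc$geno), a22$A22, 0.05)
  Ginv <- chol2inv(chol(relMatrix(G)))
  Hinv <- buildHInverse(Ainv, a22$A22inv, Ginv, gids)
  H <- solve(as.matrix(Hinv))
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(abs(Hinv - Matrix::t(Hinv))), 1e-10)
})

test_that("AI-REML agrees with the direct-V EM-REML oracle", {
  # ~200-record pedigree datasets, both components to 1e-5 relative
  for (seed in c(1, 2)) {
    cfg <- smallConfig(seed = seed, nFounders = 90L, nSnpsPerChrom = 60L,
                       qtlWindows = data.frame())
    pop <- simulatePopulation(cfg, polygenicModel = "pedigree")
    ped <- pop$ped
    ids <- animalIds(ped)
    dat <- pop$pheno[sample(nrow(pop$pheno), 200), ]
    X <- designMatrix(dat[, c("sex", "farm")])
    K <- buildA(ped)
    Kinv <- buildAInverse(ped)
    fit <- aireml(dat$y, X, dat$id, Kinv, tol = 1e-10)
    Zinc <- denseIncidence(dat$id, ids)
    em <- oracleEmReml(dat$y, X, Zinc, K)
    expect_true(fit@converged)
    expect_equal(varA(fit), em$sigmaA2, tolerance = 1e-5)
    expect_equal(varE(fit), em$sigmaE2, tolerance = 1e-5)
  }
})

test_that("balanced one-way design with K = I matches the EM-REML oracle", {
  set.seed(9)
  nGrp <- 40
  rep <- 5
  grp <- rep(sprintf("g%02d", 1:nGrp), each = rep)
  y <- rnorm(nGrp, sd = 2)[match(grp, unique(grp))] + rnorm(nGrp * rep)
  X <- designMatrix(NULL, n = length(y))
  K <- diag(nGrp)
  dimnames(K) <- list(unique(grp), unique(grp))
  fit <- aireml(y, X, grp, K, tol = 1e-10)
  em <- oracleEmReml(y, X, denseIncidence(grp, unique(grp)), K)
  expect_equal(varA(fit), em$sigmaA2, tolerance = 1e-6)
  expect_equal(varE(fit), em$sigmaE2, tolerance = 1e-6)
})

test_that("pure-noise data drives the heritability estimate to the floor", {
  est <- vapply(1:3, function(seed) {
    # deep 3-generation family pedigree of ~1000 animals carries enough
    # relatedness information to pin a null h2 near the boundary
    ped <- simulatePedigree(smallConfig(seed = seed, nFounders = 340L))
    set.seed(seed + 50)
    rec <- pedRecords(ped)
    y <- rnorm(nrow(rec)) # no genetic signal at all
    X <- designMatrix(NULL, n = length(y))
    heritability(aireml(y, X, rec$id, buildAInverse(ped)))
  }, numeric(1))
  expect_lt(mean(est), 0.05)
})

test_that("restricted log-likelihood matches the direct-V evaluation", {
  cfg <- smallConfig(seed = 31, nFounders = 60L, nSnpsPerChrom = 50L)
  pop <- simulatePopulation(cfg)
  ped <- pop$ped
  dat <- pop$pheno[sample(nrow(pop$pheno), 100), ]
  X <- designMatrix(dat[, c("sex", "farm")])
  Kinv <- buildAInverse(ped)
  fit <- aireml(dat$y, X, dat$id, Kinv)
  direct <- oracleRemlLogLik(dat$y, X, denseIncidence(dat$id, animalIds(ped)),
                             buildA(ped), varA(fit), varE(fit))
  expect_equal(fit@logLik, as.numeric(direct), tolerance = 1e-6)
})

test_that("REML components are invariant to a constant shift of the response", {
  cfg <- smallConfig(seed = 13, nFounders = 40L)
  pop <- simulatePopulation(cfg)
  dat <- pop$pheno
  X <- designMatrix(dat[, c("sex", "birthYear")])
  Kinv <- buildAInverse(pop$ped)
  f1 <- aireml(dat$y, X, dat$id, Kinv)
  f2 <- aireml(dat$y + 500, X, dat$id, Kinv)
  expect_equal(varA(f1), varA(f2), tolerance = 1e-6)
  expect_equal(varE(f1), varE(f2), tolerance = 1e-6)
  s1 <- solveMME(dat$y, X, dat$id, Kinv, f1)
  s2 <- solveMME(dat$y + 500, X, dat$id, Kinv, f1)
  expect_equal(fixedEffects(s2)[["(Intercept)"]],
               fixedEffects(s1)[["(Intercept)"]] + 500, tolerance = 1e-8)
  expect_equal(breedingValues(s1), breedingValues(s2), tolerance = 1e-8)
})

test_that("MME solution matches explicitly solved normal equations", {
  # 5 records on 2 animals plus an unphenotyped founder link
  ped <- pigPedigree(data.frame(id = c("f", "u", "v"),
                                sire = c(NA, "f", "f"), dam = NA))
  y <- c(3.2, 4.1, 2.9, 5.0, 4.4)
  animal <- c("u", "u", "v", "v", "v")
  X <- matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)"))
  Kinv <- buildAInverse(ped)
  vc <- list(sigmaA2 = 2, sigmaE2 = 3)
  sol <- solveMME(y, X, animal, Kinv, vc)
  # build the same equations longhand and solve densely
  Zinc <- denseIncidence(animal, animalIds(ped))
  M <- rbind(cbind(crossprod(X), crossprod(X, Zinc)),
             cbind(crossprod(Zinc, X),
                   crossprod(Zinc) + as.matrix(Kinv) * (3 / 2)))
  rhs <- c(crossprod(X, y), crossprod(Zinc, y))
  ref <- solve(M, rhs)
  expect_equal(unname(c(fixedEffects(sol), breedingValues(sol))),
               unname(ref), tolerance = 1e-10)
})

test_that("ssGBLUP with no genotyped animals equals pedigree BLUP (GLS oracle)", {
  cfg <- smallConfig(seed = 17, nFounders = 40L)
  pop <- simulatePopulation(cfg, polygenicModel = "pedigree")
  ped <- pop$ped
  dat <- pop$pheno
  X <- designMatrix(dat[, c("sex", "farm")])
  Kinv <- buildAInverse(ped) # H-inverse with empty genotype set
  vc <- aireml(dat$y, X, dat$id, Kinv)
  sol <- solveMME(dat$y, X, dat$id, Kinv, vc)
  ref <- oracleGlsBlup(dat$y, X, denseIncidence(dat$id, animalIds(ped)),
                       buildA(ped), varA(vc), varE(vc))
  expect_lt(max(abs(unname(breedingValues(sol)) - ref$a)), 1e-8)
  expect_lt(max(abs(unname(fixedEffects(sol)) - ref$b)), 1e-8)
})

test_that("infinite shrinkage drives all breeding values to zero", {
  sc <- ssScene(seed = 23L)
  dat <- sc$pheno
  X <- designMatrix(NULL, n = nrow(dat))
  Kinv <- buildAInverse(sc$ped)
  sol <- solveMME(dat$y, X, dat$id, Kinv,
                  list(sigmaA2 = 1e-9, sigmaE2 = 1))
  expect_lt(max(abs(breedingValues(sol))), 1e-4)
})

test_that("rank-deficient designs and bad inputs are rejected", {
  y <- rnorm(10)
  X <- cbind(1, 1) # rank 1
  K <- diag(10)
  dimnames(K) <- list(letters[1:10], letters[1:10])
  expect_error(aireml(y, X, letters[1:10], K), "rank deficient")
  expect_error(solveMME(y, matrix(1, 10, 1), letters[1:10], unname(K),
                        list(sigmaA2 = 1, sigmaE2 = 1)), "dimnames")
  expect_error(solveMME(y, matrix(1, 10, 1), c(letters[1:9], "zz"), K,
                        list(sigmaA2 = 1, sigmaE2 = 1)), "missing from")
})
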