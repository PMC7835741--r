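## Gene-dropping simulator for a Duroc-like nucleus herd: multi-generation
## pedigree, founder haplotypes with Mendelian transmission and Poisson
## recombination, planted QTL windows, pedigree-correlated polygenic
## values, and selective (youngest-first) genotyping.

## All stages draw from streams derived from the single master seed.
.stageSeed <- function(seed, stage) {
  offsets <- c(pedigree = 0L, genotypes = 1L, phenotypes = 2L, mask = 3L)
  (as.integer(seed) + 1000003L * offsets[[stage]]) %% .Machine$integer.max
}

#' Build a simulation configuration
#'
#' Defaults emulate the study population the pipeline targets: ~4200
#' animals over 3 generations (600 founders, litter size 4), 18 autosomes
#' of 140 Mb carrying 1992 evenly spaced SNPs each (~35.9 k genome-wide),
#' recombination at 1 cM/Mb, about half of the animals genotyped (youngest
#' first), heritability 0.33, fixed effects of birth year, sex and farm,
#' and four planted QTL windows contributing 1.5-3% of the additive
#' genetic variance each. The phenotype scale mimics days to 100 kg
#' (mean 163.4, SD 11.4).
#'
#' @param nFounders,nGenerations,litterSize pedigree structure;
#'   `nGenerations` counts the founder generation (1 = founders only).
#' @param nChromosomes,chromLengthBp,nSnpsPerChrom genome layout.
#' @param recombRate Morgans per 1e8 bases (1 = 1 cM/Mb).
#' @param ldLengthBp correlation length of founder-haplotype LD in bases
#'   (default 0.3 Mb, giving strong within-window and weak cross-window
#'   disequilibrium, as fits a 0.8 Mb window scan); 0 disables founder LD.
#' @param qtlCausalSnps causal SNPs sampled per QTL window (default 2); the
#'   remaining window SNPs tag them through LD.
#' @param nBackgroundLoci number of background causal loci (minor genes)
#'   carrying the polygenic remainder (default 300), drawn outside the QTL
#'   windows; a "several major genes plus many minor genes" architecture.
#' @param qtlWindows data.frame (`chrom`, `startBp`, `endBp`, `fraction`).
#' @param h2Target narrow-sense heritability in (0, 1].
#' @param traitMean,traitSD phenotype location and scale.
#' @param fixedEffectSD SD of the fixed-effect level values, relative to
#'   the phenotypic SD (0 disables fixed effects).
#' @param nFarms number of farm levels.
#' @param genotypedFraction fraction of animals keeping genotypes.
#' @param seed master seed for all stages.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nFounders = 600L, nGenerations = 3L, litterSize = 4L,
                      nChromosomes = 18L, chromLengthBp = 1.4e8,
                      nSnpsPerChrom = 1992L, recombRate = 1,
                      ldLengthBp = 3e5, qtlCausalSnps = 2L,
                      nBackgroundLoci = 300L,
                      qtlWindows = data.frame(
                        chrom = c(4L, 7L, 2L, 14L),
                        startBp = c(4.8e6, 29.6e6, 8.0e6, 2.4e6),
                        endBp = c(5.6e6, 30.4e6, 8.8e6, 3.2e6),
                        fraction = c(0.03, 0.025, 0.02, 0.015)
                      ),
                      h2Target = 0.33, traitMean = 163.4, traitSD = 11.4,
                      fixedEffectSD = 0.25, nFarms = 2L,
                      genotypedFraction = 0.53, seed = 1L) {
  cfg <- new("SimConfig",
    nFounders = as.integer(nFounders),
    nGenerations = as.integer(nGenerations),
    litterSize = as.integer(litterSize),
    nChromosomes = as.integer(nChromosomes),
    chromLengthBp = as.numeric(chromLengthBp),
    nSnpsPerChrom = as.integer(nSnpsPerChrom),
    recombRate = as.numeric(recombRate),
    ldLengthBp = as.numeric(ldLengthBp),
    qtlCausalSnps = as.integer(qtlCausalSnps),
    nBackgroundLoci = as.integer(nBackgroundLoci),
    qtlWindows = as.data.frame(qtlWindows),
    h2Target = as.numeric(h2Target),
    traitMean = as.numeric(traitMean),
    traitSD = as.numeric(traitSD),
    fixedEffectSD = as.numeric(fixedEffectSD),
    nFarms = as.integer(nFarms),
    genotypedFraction = as.numeric(genotypedFraction),
    seed = as.integer(seed)
  )
  validObject(cfg)
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) are unrelated with unknown parents and balanced
#' sexes. In each later generation every female of the previous generation
#' is mated to one randomly drawn male of that generation and produces
#' `litterSize` offspring of random sex. Birth year increments with
#' generation; farms are assigned at random.
#'
#' @param config a [SimConfig-class].
#' @return a [PigPedigree-class] (parents always precede offspring).
#' @export
simulatePedigree <- function(config) {
  validObject(config)
  set.seed(.stageSeed(config@seed, "pedigree"))
  nf <- config@nFounders
  sex0 <- rep(c("M", "F"), length.out = nf)
  rec <- data.frame(
    id = sprintf("G0_%05d", seq_len(nf)),
    sire = NA_character_, dam = NA_character_,
    sex = sex0, birthYear = 2015L,
    farm = paste0("farm", sample.int(config@nFarms, nf, replace = TRUE)),
    generation = 0L, stringsAsFactors = FALSE
  )
  prev <- rec
  for (g in seq_len(config@nGenerations - 1L)) {
    sires <- prev$id[prev$sex == "M"]
    dams <- prev$id[prev$sex == "F"]
    if (!length(sires) || !length(dams)) {
      stop("generation ", g - 1L, " has no available sires or dams")
    }
    mateSire <- sample(sires, length(dams), replace = TRUE)
    nOff <- length(dams) * config@litterSize
    off <- data.frame(
      id = sprintf("G%d_%05d", g, seq_len(nOff)),
      sire = rep(mateSire, each = config@litterSize),
      dam = rep(dams, each = config@litterSize),
      sex = sample(c("M", "F"), nOff, replace = TRUE),
      birthYear = 2015L + g,
      farm = paste0("farm", sample.int(config@nFarms, nOff, replace = TRUE)),
      generation = g, stringsAsFactors = FALSE
    )
    rec <- rbind(rec, off)
    prev <- off
  }
  new("PigPedigree", records = rec)
}

## one gamete: recombination mosaic of the parent's two chromosome copies
.gamete <- function(h1, h2, pos, lenBp, morgans) {
  nx <- rpois(1L, morgans)
  start <- sample.int(2L, 1L)
  if (nx == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  xpos <- sort(runif(nx, 0, lenBp))
  seg <- findInterval(pos, xpos)
  ifelse((seg + start) %% 2L == 1L, h1, h2)
}

## founder haplotypes with local LD: a latent AR(1) Gaussian along the
## chromosome (correlation exp(-gap/ldLengthBp)) thresholded at the
## per-SNP allele frequency, so marginals stay at pf while nearby SNPs
## are in disequilibrium
.founderHaplotypes <- function(nHap, pf, pos, ldLengthBp) {
  m <- length(pf)
  if (ldLengthBp <= 0) {
    return(matrix(rbinom(nHap * m, 1L, rep(pf, each = nHap)), nHap, m))
  }
  z <- matrix(0, nHap, m)
  z[, 1] <- rnorm(nHap)
  if (m > 1) {
    phi <- exp(-diff(pos) / ldLengthBp)
    for (j in 2:m) {
      z[, j] <- phi[j - 1] * z[, j - 1] +
        sqrt(1 - phi[j - 1]^2) * rnorm(nHap)
    }
  }
  (z < rep(qnorm(pf), each = nHap)) + 0L
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotype alleles are drawn per SNP from Uniform(0.1, 0.9)
#' allele frequencies (a post-QC-like MAF spectrum), with local linkage
#' disequilibrium among founders generated by a latent first-order
#' autoregressive process whose correlation decays as
#' `exp(-distance / ldLengthBp)` -- nearby SNPs tag each other, distant
#' ones are nearly independent, as in a real dense panel. Every offspring
#' receives one recombinant gamete from each parent: crossovers are a
#' Poisson process along the chromosome at `recombRate` (no interference).
#' Markers are evenly spaced along each chromosome.
#'
#' @param ped a [PigPedigree-class] from [simulatePedigree()].
#' @param config the matching [SimConfig-class].
#' @return a [GenotypeData-class] for all animals; founder allele
#'   frequencies are attached as attribute `"founderFreq"`.
#' @export
simulateGenotypes <- function(ped, config) {
  set.seed(.stageSeed(config@seed, "genotypes"))
  rec <- pedRecords(ped)
  pidx <- .parentIdx(ped)
  n <- nrow(rec)
  mC <- config@nSnpsPerChrom
  spacing <- config@chromLengthBp / mC
  posC <- round((seq_len(mC) - 0.5) * spacing)
  morgans <- config@recombRate * config@chromLengthBp / 1e8
  founder <- is.na(pidx$s) & is.na(pidx$d)

  dosList <- vector("list", config@nChromosomes)
  mapList <- vector("list", config@nChromosomes)
  pAll <- numeric(0)
  for (cc in seq_len(config@nChromosomes)) {
    pf <- runif(mC, 0.1, 0.9)
    pAll <- c(pAll, pf)
    H1 <- matrix(0L, n, mC)
    H2 <- matrix(0L, n, mC)
    nf <- sum(founder)
    FH <- .founderHaplotypes(2L * nf, pf, posC, config@ldLengthBp)
    H1[founder, ] <- FH[seq_len(nf), ]
    H2[founder, ] <- FH[nf + seq_len(nf), ]
    for (i in which(!founder)) {
      s <- pidx$s[i]
      d <- pidx$d[i]
      if (is.na(s) || is.na(d)) {
        stop("animal ", rec$id[i], " has a missing parent reference; ",
             "gene dropping needs both parents or none")
      }
      H1[i, ] <- .gamete(H1[s, ], H2[s, ], posC, config@chromLengthBp, morgans)
      H2[i, ] <- .gamete(H1[d, ], H2[d, ], posC, config@chromLengthBp, morgans)
    }
    dosList[[cc]] <- H1 + H2
    mapList[[cc]] <- data.frame(
      snp = sprintf("snp%d_%05d", cc, seq_len(mC)),
      chrom = as.character(cc), pos = posC, stringsAsFactors = FALSE
    )
  }
  dosageM <- do.call(cbind, dosList)
  map <- do.call(rbind, mapList)
  rownames(dosageM) <- rec$id
  colnames(dosageM) <- map$snp
  geno <- new("GenotypeData", dosage = dosageM, map = map)
  attr(geno, "founderFreq") <- pAll
  geno
}

## pedigree-correlated polygenic deviates: parental average plus a
## Mendelian-sampling draw whose variance shrinks with parental inbreeding
.polygenic <- function(ped) {
  pidx <- .parentIdx(ped)
  F <- unname(inbreeding(ped))
  n <- length(pidx$ids)
  s <- pidx$s
  d <- pidx$d
  msSD <- sqrt(ifelse(!is.na(s) & !is.na(d),
                      0.5 - 0.25 * (F[ifelse(is.na(s), 1L, s)] +
                                    F[ifelse(is.na(d), 1L, d)]),
                      1))
  z <- rnorm(n)
  u <- numeric(n)
  for (i in seq_len(n)) {
    pa <- 0
    if (!is.na(s[i]) && !is.na(d[i])) pa <- 0.5 * (u[s[i]] + u[d[i]])
    u[i] <- pa + msSD[i] * z[i]
  }
  u
}

.popVar <- function(x) mean((x - mean(x))^2)

## centered genotypic value Z beta computed in column blocks to avoid a
## full double copy of the dosage matrix
.genomicValue <- function(M, beta, blockSize = 2000L) {
  n <- nrow(M)
  out <- numeric(n)
  m <- ncol(M)
  for (from in seq(1L, m, by = blockSize)) {
    cols <- from:min(from + blockSize - 1L, m)
    Zb <- sweep(M[, cols, drop = FALSE], 2, colMeans(M[, cols, drop = FALSE]),
                "-")
    out <- out + as.numeric(Zb %*% beta[cols])
  }
  out
}

#' Simulate phenotypes with planted QTL
#'
#' Breeding values are the sum of (i) per-window QTL genotypic values --
#' every SNP inside a QTL window receives a normal allele-substitution
#' effect, rescaled so the window contributes exactly its target fraction
#' of the additive variance -- and (ii) a polygenic remainder carrying the
#' rest. By default the remainder is genomic: small normal effects on
#' every SNP outside the QTL windows, over the gene-dropped genotypes of
#' *all* animals, so ungenotyped ancestors carry genetic signal through
#' inheritance as single-step evaluation requires, and the genomic
#' relationship matrix is the correct covariance kernel for the simulated
#' trait. `polygenicModel = "pedigree"` instead draws the remainder by the
#' parental-average + Mendelian-sampling recursion on the pedigree
#' (uncoupled from the marker genome). Residual variance is scaled to hit
#' `h2Target`; birth-year, sex and farm level effects are added, and the
#' result is expressed on the configured trait scale.
#'
#' @param ped a [PigPedigree-class].
#' @param geno the matching all-animal [GenotypeData-class].
#' @param config the [SimConfig-class] used to generate both.
#' @param polygenicModel `"genomic"` (default) or `"pedigree"`, see above.
#' @return list with `pheno` (data.frame `id`, `y`, `sex`, `birthYear`,
#'   `farm`) and `truth` (list: named `breedingValues`, `qtlEffects`
#'   data.frame, `realizedH2`, `sigmaA2`, `sigmaE2`, per-window
#'   `windowFractions`).
#' @export
simulatePhenotypes <- function(ped, geno, config,
                               polygenicModel = c("genomic", "pedigree")) {
  polygenicModel <- match.arg(polygenicModel)
  set.seed(.stageSeed(config@seed, "phenotypes"))
  rec <- pedRecords(ped)
  map <- markerMap(geno)
  qw <- config@qtlWindows
  h2 <- config@h2Target
  n <- nrow(rec)

  inAnyQtl <- rep(FALSE, nrow(map))
  if (nrow(qw)) {
    for (k in seq_len(nrow(qw))) {
      inAnyQtl <- inAnyQtl | (map$chrom == as.character(qw$chrom[k]) &
                                map$pos >= qw$startBp[k] &
                                map$pos < qw$endBp[k])
    }
  }
  poly <- if (polygenicModel == "genomic") {
    bg <- which(!inAnyQtl)
    if (config@nBackgroundLoci < length(bg)) {
      bg <- sort(sample(bg, config@nBackgroundLoci))
    }
    betaPoly <- numeric(nrow(map))
    betaPoly[bg] <- rnorm(length(bg))
    .genomicValue(dosage(geno), betaPoly)
  } else {
    .polygenic(ped)
  }
  fPoly <- 1 - sum(qw$fraction)
  poly <- poly * sqrt(fPoly / .popVar(poly))

  bv <- poly
  qtlEffects <- data.frame(snp = character(), effect = numeric(),
                           window = integer(), stringsAsFactors = FALSE)
  windowValues <- NULL
  if (nrow(qw)) {
    windowValues <- matrix(0, n, nrow(qw))
    for (k in seq_len(nrow(qw))) {
      inWin <- map$chrom == as.character(qw$chrom[k]) &
        map$pos >= qw$startBp[k] & map$pos < qw$endBp[k]
      if (!any(inWin)) {
        stop("QTL window ", k, " (chr", qw$chrom[k], ":", qw$startBp[k], "-",
             qw$endBp[k], ") contains no SNPs; target fraction unattainable")
      }
      ## concentrate the window's variance on a few causal SNPs; the rest
      ## of the window tags them through LD
      causal <- sort(sample(which(inWin),
                            min(config@qtlCausalSnps, sum(inWin))))
      inWin <- rep(FALSE, length(inWin))
      inWin[causal] <- TRUE
      Zk <- centerDosages(dosage(geno)[, inWin, drop = FALSE])
      beta <- rnorm(sum(inWin))
      wk <- as.numeric(Zk %*% beta)
      scale_k <- sqrt(qw$fraction[k] / .popVar(wk))
      beta <- beta * scale_k
      wk <- wk * scale_k
      windowValues[, k] <- wk
      bv <- bv + wk
      qtlEffects <- rbind(qtlEffects, data.frame(
        snp = map$snp[inWin], effect = beta, window = k,
        stringsAsFactors = FALSE
      ))
    }
  }

  varBv <- .popVar(bv)
  varE <- if (h2 >= 1) 0 else varBv * (1 - h2) / h2
  e <- if (varE > 0) rnorm(n, 0, sqrt(varE)) else numeric(n)

  sdP <- sqrt(varBv + varE)
  feSD <- config@fixedEffectSD * sdP
  fx <- numeric(n)
  if (feSD > 0) {
    for (col in c("birthYear", "sex", "farm")) {
      lev <- unique(rec[[col]])
      eff <- setNames(rnorm(length(lev), 0, feSD), lev)
      fx <- fx + unname(eff[as.character(rec[[col]])])
    }
  }

  sc <- config@traitSD / sdP
  y <- config@traitMean + sc * (bv + e + fx)
  truth <- list(
    breedingValues = setNames(sc * bv, rec$id),
    qtlEffects = transform(qtlEffects, effect = effect * sc),
    realizedH2 = varBv / (varBv + varE),
    sigmaA2 = sc^2 * varBv,
    sigmaE2 = sc^2 * varE,
    windowFractions = if (nrow(qw)) {
      apply(windowValues, 2, .popVar) / varBv
    } else numeric(0)
  )
  pheno <- data.frame(
    id = rec$id, y = y, sex = rec$sex,
    birthYear = rec$birthYear, farm = rec$farm, stringsAsFactors = FALSE
  )
  list(pheno = pheno, truth = truth)
}

#' Drop genotypes for a fraction of animals (selective genotyping)
#'
#' Keeps genotypes for `round(fraction * n)` animals, preferring the
#' youngest generations (ties within the cut generation resolved at
#' random under `seed`), mirroring nucleus-herd practice where the
#' youngest selection candidates are genotyped. Row order of the retained
#' animals is preserved, so `fraction = 1` is the identity.
#'
#' @param geno a [GenotypeData-class] covering all animals.
#' @param fraction fraction of animals to keep, in (0, 1].
#' @param seed seed for the within-generation tie-break.
#' @param ped optional [PigPedigree-class] supplying generation/birth-year
#'   ordering; without it, later rows are treated as younger.
#' @return the subset [GenotypeData-class].
#' @export
maskGenotypes <- function(geno, fraction, seed = 1L, ped = NULL) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must lie in (0, 1]")
  ids <- animalIds(geno)
  n <- length(ids)
  nKeep <- round(fraction * n)
  if (fraction == 1 || nKeep >= n) return(geno)
  set.seed(.stageSeed(seed, "mask"))
  age <- if (!is.null(ped)) {
    rec <- pedRecords(ped)
    key <- if ("generation" %in% names(rec)) rec$generation else rec$birthYear
    setNames(key, rec$id)[ids]
  } else {
    seq_len(n)
  }
  ord <- order(-as.numeric(age), sample.int(n)) # youngest first, random ties
  keep <- sort(ord[seq_len(nKeep)])
  new("GenotypeData", dosage = dosage(geno)[keep, , drop = FALSE],
      map = markerMap(geno))
}

#' Simulate a complete study population
#'
#' Runs [simulatePedigree()], [simulateGenotypes()],
#' [simulatePhenotypes()] and [maskGenotypes()] under the config's master
#' seed and returns every piece the downstream pipeline needs.
#'
#' @param config a [SimConfig-class].
#' @param polygenicModel passed to [simulatePhenotypes()].
#' @return list: `ped`, `genoFull` (all animals), `geno` (genotyped
#'   subset), `pheno`, `truth`, `config`.
#' @export
simulatePopulation <- function(config, polygenicModel = "genomic") {
  ped <- simulatePedigree(config)
  genoFull <- simulateGenotypes(ped, config)
  ph <- simulatePhenotypes(ped, genoFull, config, polygenicModel)
  geno <- maskGenotypes(genoFull, config@genotypedFraction,
                        seed = config@seed, ped = ped)
  list(ped = ped, genoFull = genoFull, geno = geno,
       pheno = ph$pheno, truth = ph$truth, config = config)
}
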