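## Plain-text readers/writers (pedigree CSV, phenotype CSV, PLINK PED/MAP)
## and the end-to-end pipeline driver.

#' Read a pedigree CSV
#'
#' Expected columns: `id`, `sire`, `dam`, optionally `sex`, `birthYear`,
#' `farm`, `generation`. `0`, empty and `NA` mark unknown parents. Records
#' are topologically sorted on read.
#'
#' @param path CSV file path.
#' @return a [PigPedigree-class].
#' @export
readPedigree <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  pigPedigree(df) # id/sire/dam coerced to character there
}

#' Write a pedigree CSV
#' @param ped a [PigPedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  data.table::fwrite(pedRecords(ped), path)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Needs an `id` column; all other columns pass through (the response and
#' fixed-effect covariates are picked by name downstream).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!"id" %in% names(df)) stop("phenotype file needs an 'id' column")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate phenotype records for an animal")
  df
}

#' Write genotypes as PLINK PED/MAP text files
#'
#' Biallelic A/B coding: dosage counts the B allele (0 = "A A",
#' 1 = "A B", 2 = "B B", missing = "0 0"). The MAP file carries
#' chromosome, SNP id, a zero genetic distance, and the bp position.
#'
#' @param geno a [GenotypeData-class].
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param fam optional data.frame (`id`, `sire`, `dam`, `sex`) for the PED
#'   family columns; unknown fields are written as 0.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(geno, prefix, fam = NULL) {
  M <- dosage(geno)
  map <- markerMap(geno)
  ids <- rownames(M)
  if (is.null(fam)) {
    fam <- data.frame(id = ids, sire = "0", dam = "0", sex = "0",
                      stringsAsFactors = FALSE)
  } else {
    fam <- fam[match(ids, fam$id), , drop = FALSE]
    fam$sire[is.na(fam$sire)] <- "0"
    fam$dam[is.na(fam$dam)] <- "0"
    fam$sex <- ifelse(is.na(fam$sex), "0",
                      ifelse(fam$sex == "M", "1",
                             ifelse(fam$sex == "F", "2", "0")))
  }
  codes <- c("A A", "A B", "B B")
  alleles <- matrix("0 0", nrow(M), ncol(M))
  ok <- !is.na(M)
  alleles[ok] <- codes[M[ok] + 1L]
  ped <- cbind(fam$id, fam$id, fam$sire, fam$dam, fam$sex, "-9", alleles)
  data.table::fwrite(as.data.frame(ped), paste0(prefix, ".ped"),
                     sep = " ", col.names = FALSE, quote = FALSE)
  data.table::fwrite(
    data.frame(chrom = map$chrom, snp = map$snp, cm = 0, pos = map$pos),
    paste0(prefix, ".map"), sep = "\t", col.names = FALSE, quote = FALSE
  )
  invisible(prefix)
}

#' Read PLINK PED/MAP text files
#'
#' Parses biallelic genotypes into 0/1/2 dosages counting the
#' lexicographically later allele at each SNP (so A/B coding counts B);
#' `0` alleles mark missing genotypes. Malformed lines (wrong column
#' count, half-missing genotypes) are reported with their line number.
#'
#' @param prefix path prefix of `<prefix>.ped` and `<prefix>.map`.
#' @return list with `geno` (a [GenotypeData-class]) and `fam`
#'   (data.frame `id`, `sire`, `dam`, `sex`).
#' @export
readPlink <- function(prefix) {
  mapFile <- paste0(prefix, ".map")
  pedFile <- paste0(prefix, ".ped")
  if (!file.exists(mapFile) || !file.exists(pedFile)) {
    stop("missing ", mapFile, " or ", pedFile)
  }
  map <- data.table::fread(mapFile, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  if (ncol(map) != 4) stop("MAP file must have 4 columns")
  map <- data.frame(snp = map[[2]], chrom = map[[1]],
                    pos = as.numeric(map[[4]]), stringsAsFactors = FALSE)
  m <- nrow(map)
  ped <- data.table::fread(pedFile, header = FALSE, data.table = FALSE,
                           colClasses = "character", sep = " ")
  bad <- which(rowSums(!is.na(ped)) != 6 + 2 * m)
  if (ncol(ped) != 6 + 2 * m || length(bad)) {
    stop("PED line ", if (length(bad)) bad[1] else 1,
         ": expected ", 6 + 2 * m, " fields (6 + 2 alleles per SNP)")
  }
  ids <- ped[[2]]
  if (anyDuplicated(ids)) stop("duplicate animal ids in PED file")
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  halfMissing <- xor(a1 == "0", a2 == "0")
  if (any(halfMissing)) {
    stop("PED line ", which(rowSums(halfMissing) > 0)[1],
         ": half-missing genotype")
  }
  dosageM <- matrix(NA_real_, nrow(ped), m)
  for (j in seq_len(m)) {
    obs <- a1[, j] != "0"
    alleles <- sort(unique(c(a1[obs, j], a2[obs, j])))
    if (length(alleles) > 2) {
      stop("SNP ", map$snp[j], " has more than two alleles")
    }
    counted <- alleles[length(alleles)] # lexicographically later allele
    dosageM[obs, j] <- (a1[obs, j] == counted) + (a2[obs, j] == counted)
  }
  rownames(dosageM) <- ids
  colnames(dosageM) <- map$snp
  sex <- ifelse(ped[[5]] == "1", "M", ifelse(ped[[5]] == "2", "F", NA))
  fam <- data.frame(id = ids, sire = ped[[3]], dam = ped[[4]], sex = sex,
                    stringsAsFactors = FALSE)
  fam$sire[fam$sire == "0"] <- NA
  fam$dam[fam$dam == "0"] <- NA
  list(geno = genotypeData(dosageM, map), fam = fam)
}

#' Write a simulated population to plain-text files
#'
#' Pedigree and phenotypes as CSV, genotypes of the genotyped subset as
#' PLINK PED/MAP, and the simulation truth (breeding values, QTL effects)
#' as sidecar TSVs.
#'
#' @param pop result of [simulatePopulation()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePopulation <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePedigree(pop$ped, file.path(dir, "pedigree.csv"))
  data.table::fwrite(pop$pheno, file.path(dir, "phenotypes.csv"))
  rec <- pedRecords(pop$ped)
  writePlink(pop$geno, file.path(dir, "genotypes"),
             fam = rec[, c("id", "sire", "dam", "sex")])
  data.table::fwrite(
    data.frame(id = names(pop$truth$breedingValues),
               tbv = unname(pop$truth$breedingValues)),
    file.path(dir, "true_breeding_values.tsv"), sep = "\t"
  )
  data.table::fwrite(pop$truth$qtlEffects,
                     file.path(dir, "true_qtl_effects.tsv"), sep = "\t")
  invisible(dir)
}

#' Read and cross-validate the three pipeline inputs
#'
#' Reads pedigree CSV, phenotype CSV and PLINK genotypes, then checks id
#' consistency: genotyped or phenotyped animals absent from the pedigree
#' are an error.
#'
#' @param pedFile pedigree CSV path.
#' @param phenoFile phenotype CSV path.
#' @param plinkPrefix PLINK PED/MAP prefix.
#' @return list with `ped`, `pheno`, `geno`.
#' @export
readInputs <- function(pedFile, phenoFile, plinkPrefix) {
  ped <- readPedigree(pedFile)
  pheno <- readPhenotypes(phenoFile)
  geno <- readPlink(plinkPrefix)$geno
  ids <- animalIds(ped)
  orphanG <- setdiff(animalIds(geno), ids)
  if (length(orphanG)) {
    stop("genotyped animal(s) not in pedigree: ",
         paste(utils::head(orphanG, 5), collapse = ", "))
  }
  orphanP <- setdiff(pheno$id, ids)
  if (length(orphanP)) {
    stop("phenotype for unknown animal(s): ",
         paste(utils::head(orphanP, 5), collapse = ", "))
  }
  list(ped = ped, pheno = pheno, geno = geno)
}

#' Run the full single-step association pipeline
#'
#' Stage order: (optional) trait adjustment, genotype QC, variance
#' components under both pedigree BLUP (A-inverse) and ssGBLUP (H-inverse),
#' then the weighted single-step scan using the ssGBLUP components. All
#' tables are returned and, when `outDir` is given, written as TSV
#' alongside a run manifest of per-stage record counts.
#'
#' @param ped a [PigPedigree-class].
#' @param geno raw [GenotypeData-class] of the genotyped animals.
#' @param pheno data.frame with `id`, the response column, and fixed-effect
#'   columns; pass raw measurements through [adjustTraits()] first when
#'   starting from unadjusted weights.
#' @param trait name of the response column in `pheno` (e.g. `"age100"`).
#' @param fixed fixed-effect column names (default sex, birth year, farm
#'   where present).
#' @param outDir optional output directory.
#' @param nIterations,alpha,windowSize,threshold,flankBp scan parameters.
#' @param qcArgs list of [qcFilter()] threshold overrides.
#' @return list: `fit` ([WssGwasFit-class]), `vcBlup`, `vcSsgblup`,
#'   `regions`, `qcReport`, `manifest`.
#' @export
runPipeline <- function(ped, geno, pheno, trait = "y",
                        fixed = intersect(c("sex", "birthYear", "farm"),
                                          names(pheno)),
                        outDir = NULL, nIterations = 3L, alpha = 0.05,
                        windowSize = 8e5, threshold = 1.0, flankBp = 4e5,
                        qcArgs = list()) {
  if (!trait %in% names(pheno)) {
    stop("trait column '", trait, "' not found in phenotypes; for LMP ",
         "supply adjusted BF/LMD via adjustTraits() first")
  }
  if (!all(pheno$id %in% animalIds(ped))) {
    stop("phenotyped animal(s) missing from the pedigree")
  }
  if (!all(animalIds(geno) %in% animalIds(ped))) {
    stop("genotyped animal(s) missing from the pedigree")
  }
  pheno <- pheno[is.finite(pheno[[trait]]), , drop = FALSE]
  qc <- do.call(qcFilter, c(list(geno = geno), qcArgs))
  genoQc <- qc$geno
  message(sprintf("QC: %d animals, %d SNPs retained",
                  nAnimals(genoQc), ncol(dosage(genoQc))))

  dat <- pheno
  dat$y <- dat[[trait]]
  X <- if (length(fixed)) designMatrix(dat[, fixed, drop = FALSE]) else {
    designMatrix(NULL, n = nrow(dat))
  }

  Ainv <- buildAInverse(ped)
  vcBlup <- aireml(dat$y, X, dat$id, Ainv)

  fit <- runWssGwas(ped, genoQc, dat, fixed = if (length(fixed)) fixed,
                    nIterations = nIterations, alpha = alpha,
                    windowSize = windowSize)
  vcSs <- fit@vc
  chromLen <- tapply(markerMap(genoQc)$pos, markerMap(genoQc)$chrom, max)
  regions <- reportRegions(windowVariances(fit), threshold = threshold,
                           flankBp = flankBp,
                           chromLengths = chromLen + windowSize)

  manifest <- list(
    package = as.character(utils::packageVersion("wssgwas")),
    trait = trait, fixed = fixed,
    nPedigree = nAnimals(ped),
    nPhenotyped = nrow(dat),
    nGenotypedRaw = nAnimals(geno),
    nGenotypedQc = nAnimals(genoQc),
    nSnpsRaw = ncol(dosage(geno)),
    nSnpsQc = ncol(dosage(genoQc)),
    nWindows = nrow(windowVariances(fit)),
    nSignificant = nrow(regions$significant),
    scan = list(nIterations = nIterations, alpha = alpha,
                windowSize = windowSize, threshold = threshold,
                flankBp = flankBp)
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    vcTab <- data.frame(
      model = c("BLUP", "ssGBLUP"),
      sigmaA2 = c(varA(vcBlup), varA(vcSs)),
      sigmaE2 = c(varE(vcBlup), varE(vcSs)),
      sigmaP2 = c(varA(vcBlup) + varE(vcBlup), varA(vcSs) + varE(vcSs)),
      h2 = c(heritability(vcBlup), heritability(vcSs)),
      seH2 = c(vcBlup@seH2, vcSs@seH2)
    )
    data.table::fwrite(vcTab, file.path(outDir, "variance_components.tsv"),
                       sep = "\t")
    data.table::fwrite(qc$report, file.path(outDir, "qc_report.tsv"),
                       sep = "\t")
    ebv <- data.frame(id = names(breedingValues(fit@solution)),
                      gebv = unname(breedingValues(fit@solution)))
    data.table::fwrite(ebv, file.path(outDir, "gebv.tsv"), sep = "\t")
    eff <- fit@state@history[[nIterations]]$effects
    eff <- cbind(markerMap(genoQc)[, c("chrom", "pos")], eff)
    data.table::fwrite(eff, file.path(outDir, "snp_effects.tsv"), sep = "\t")
    data.table::fwrite(windowVariances(fit),
                       file.path(outDir, "window_variance.tsv"), sep = "\t")
    data.table::fwrite(regions$topRegions,
                       file.path(outDir, "top_regions.tsv"), sep = "\t")
    writeLines(
      paste(names(unlist(manifest)), unlist(manifest), sep = "\t"),
      file.path(outDir, "manifest.tsv")
    )
  }
  list(fit = fit, vcBlup = vcBlup, vcSsgblup = vcSs, regions = regions,
       qcReport = qc$report, manifest = manifest)
}
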