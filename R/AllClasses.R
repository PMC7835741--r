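#' @import methods
#' @importFrom stats var rnorm rbinom runif rpois pchisq setNames model.matrix
#'   complete.cases aggregate
#' @importFrom Matrix sparseMatrix forceSymmetric crossprod t diag Diagonal
#'   solve determinant
NULL

#' Simulation configuration for a Duroc-like pig population
#'
#' Holds every tunable of the gene-dropping simulator: pedigree structure,
#' genome layout, recombination rate, planted QTL windows, target
#' heritability, fixed-effect structure and the master seed. Defaults emulate
#' a nucleus Duroc herd: roughly four thousand animals over three
#' generations, about half of them genotyped (youngest first), 18 autosomes
#' carrying ~2000 SNPs each, and a moderately heritable growth trait
#' (h2 = 0.33) measured once per animal.
#'
#' @slot nFounders number of unrelated, non-inbred founder animals.
#' @slot nGenerations total number of generations including the founders
#'   (1 = founders only).
#' @slot litterSize offspring per mating.
#' @slot nChromosomes number of autosomes simulated.
#' @slot chromLengthBp physical length of every chromosome, in bases.
#' @slot nSnpsPerChrom markers per chromosome, uniformly spaced.
#' @slot recombRate recombination rate in Morgans per 1e8 bases
#'   (1 corresponds to the usual 1 cM/Mb).
#' @slot ldLengthBp correlation length (bases) of founder-haplotype linkage
#'   disequilibrium; 0 gives founders with independent SNPs.
#' @slot qtlCausalSnps number of causal SNPs drawn per QTL window.
#' @slot nBackgroundLoci number of background (minor-gene) causal loci
#'   carrying the polygenic remainder under the genomic polygenic model.
#' @slot qtlWindows data.frame with columns `chrom`, `startBp`, `endBp`,
#'   `fraction`: each row plants a QTL whose SNP effects are scaled so the
#'   window contributes `fraction` of the additive genetic variance.
#' @slot h2Target narrow-sense heritability the phenotypes are scaled to.
#' @slot traitMean,traitSD location/scale the phenotype is expressed on
#'   (defaults mimic days to 100 kg: mean ~163 d, SD ~11.4 d).
#' @slot fixedEffectSD SD of fixed-effect level values relative to the
#'   phenotypic SD (0 disables fixed effects).
#' @slot nFarms number of farm levels (fixed effect).
#' @slot genotypedFraction fraction of animals retaining genotypes.
#' @slot seed master seed; all stages draw from streams derived from it.
#' @seealso [simConfig()], [simulatePopulation()]
#' @export
setClass("SimConfig", representation(
  nFounders = "integer",
  nGenerations = "integer",
  litterSize = "integer",
  nChromosomes = "integer",
  chromLengthBp = "numeric",
  nSnpsPerChrom = "integer",
  recombRate = "numeric",
  ldLengthBp = "numeric",
  qtlCausalSnps = "integer",
  nBackgroundLoci = "integer",
  qtlWindows = "data.frame",
  h2Target = "numeric",
  traitMean = "numeric",
  traitSD = "numeric",
  fixedEffectSD = "numeric",
  nFarms = "integer",
  genotypedFraction = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(
    nFounders = object@nFounders, nGenerations = object@nGenerations,
    litterSize = object@litterSize, nChromosomes = object@nChromosomes,
    nSnpsPerChrom = object@nSnpsPerChrom, nFarms = object@nFarms
  )
  if (any(cnt < 1L)) {
    msg <- c(msg, paste("counts must be positive:",
                        paste(names(cnt)[cnt < 1L], collapse = ", ")))
  }
  if (object@chromLengthBp <= 0) msg <- c(msg, "chromLengthBp must be positive")
  if (object@recombRate < 0) msg <- c(msg, "recombRate must be non-negative")
  if (object@ldLengthBp < 0) msg <- c(msg, "ldLengthBp must be non-negative")
  if (object@qtlCausalSnps < 1) msg <- c(msg, "qtlCausalSnps must be positive")
  if (object@nBackgroundLoci < 1) {
    msg <- c(msg, "nBackgroundLoci must be positive")
  }
  if (!(object@h2Target > 0 && object@h2Target <= 1)) {
    msg <- c(msg, "h2Target must lie in (0, 1]")
  }
  if (object@fixedEffectSD < 0) msg <- c(msg, "fixedEffectSD must be >= 0")
  if (!(object@genotypedFraction > 0 && object@genotypedFraction <= 1)) {
    msg <- c(msg, "genotypedFraction must lie in (0, 1]")
  }
  qw <- object@qtlWindows
  if (nrow(qw)) {
    need <- c("chrom", "startBp", "endBp", "fraction")
    if (!all(need %in% names(qw))) {
      msg <- c(msg, "qtlWindows needs columns chrom, startBp, endBp, fraction")
    } else {
      if (any(qw$fraction <= 0)) msg <- c(msg, "QTL fractions must be positive")
      if (sum(qw$fraction) >= 1) {
        msg <- c(msg, "QTL variance fractions must sum to < 1")
      }
      if (any(qw$chrom > object@nChromosomes | qw$chrom < 1)) {
        msg <- c(msg, "QTL window chromosome outside simulated genome")
      }
      if (any(qw$endBp > object@chromLengthBp | qw$startBp < 0)) {
        msg <- c(msg, "QTL window outside chromosome bounds")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ordered pedigree with fixed-effect covariates
#'
#' An ordered table of animal records: every parent appears before any of
#' its offspring, unknown parents are `NA`, and each animal carries the
#' covariates used as fixed effects downstream (sex, birth year, farm).
#'
#' @slot records data.frame with columns `id`, `sire`, `dam` (character,
#'   `NA` = unknown), `sex` ("M"/"F"), `birthYear`, `farm`, `generation`.
#' @seealso [readPedigree()], [simulatePedigree()], [buildA()]
#' @export
setClass("PigPedigree", representation(records = "data.frame"))

setValidity("PigPedigree", function(object) {
  rec <- object@records
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(rec))) {
    return("records needs at least columns id, sire, dam")
  }
  if (anyDuplicated(rec$id)) return("duplicate animal ids")
  pos <- seq_len(nrow(rec))
  names(pos) <- rec$id
  sp <- pos[rec$sire]
  dp <- pos[rec$dam]
  known_s <- !is.na(rec$sire)
  known_d <- !is.na(rec$dam)
  if (any(is.na(sp[known_s]))) return("sire id not present in pedigree")
  if (any(is.na(dp[known_d]))) return("dam id not present in pedigree")
  if (any(sp[known_s] >= pos[known_s]) || any(dp[known_d] >= pos[known_d])) {
    return("parents must precede offspring (no animal can be its own ancestor)")
  }
  if ("sex" %in% names(rec)) {
    sx <- setNames(rec$sex, rec$id)
    if (any(sx[rec$sire[known_s]] != "M", na.rm = TRUE)) {
      return("a sire is not recorded as male")
    }
    if (any(sx[rec$dam[known_d]] != "F", na.rm = TRUE)) {
      return("a dam is not recorded as female")
    }
  }
  TRUE
})

#' SNP dosages with a marker map
#'
#' Allele dosages (0/1/2 copies of the counted allele, `NA` = missing) for a
#' set of animals, rows in pedigree-file order, together with the marker map
#' (chromosome and physical bp position per SNP).
#'
#' @slot dosage numeric matrix, animals x SNPs, dimnames = animal ids x SNP ids.
#' @slot map data.frame with columns `snp`, `chrom`, `pos` (1-based bp).
#' @seealso [readPlink()], [qcFilter()], [buildG()]
#' @export
setClass("GenotypeData", representation(dosage = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!all(c("snp", "chrom", "pos") %in% names(object@map))) {
    msg <- c(msg, "map needs columns snp, chrom, pos")
  } else {
    if (ncol(object@dosage) != nrow(object@map)) {
      msg <- c(msg, "map length must equal number of dosage columns")
    }
    if (any(object@map$pos < 0, na.rm = TRUE)) {
      msg <- c(msg, "positions must be non-negative")
    }
    if (is.unsorted(order(object@map$chrom, object@map$pos)) &&
        any(unlist(tapply(object@map$pos, object@map$chrom, is.unsorted)))) {
      msg <- c(msg, "positions must be sorted within chromosome")
    }
  }
  rng <- range(object@dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    msg <- c(msg, "dosages must lie in [0, 2]")
  }
  if (length(msg)) msg else TRUE
})

#' Genomic relationship matrix with its scaling metadata
#'
#' The (optionally weighted, optionally blended) VanRaden genomic
#' relationship matrix \eqn{G = Z D Z' / \sum_i 2 p_i (1 - p_i)} over the
#' genotyped animals, with the allele frequencies and SNP weights used to
#' build it, so SNP effects can later be back-solved consistently.
#'
#' @slot G symmetric numeric matrix over genotyped animals.
#' @slot p counted-allele frequency per SNP.
#' @slot sum2pq the scaling constant \eqn{\sum_i 2 p_i (1 - p_i)}.
#' @slot weights diagonal SNP weight vector D used.
#' @slot alpha blending weight toward A22 that was applied (0 = unblended).
#' @seealso [buildG()], [blendG()], [backsolveSnpEffects()]
#' @export
setClass("GenomicMatrix", representation(
  G = "matrix", p = "numeric", sum2pq = "numeric",
  weights = "numeric", alpha = "numeric"
))

setValidity("GenomicMatrix", function(object) {
  msg <- character()
  if (nrow(object@G) != ncol(object@G)) msg <- c(msg, "G must be square")
  if (length(object@p) != length(object@weights)) {
    msg <- c(msg, "p and weights must have one entry per SNP")
  }
  if (object@sum2pq <= 0) msg <- c(msg, "sum2pq must be positive")
  if (any(object@weights < 0)) msg <- c(msg, "SNP weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' REML variance components for the single-trait animal model
#'
#' Additive and residual variances with the derived narrow-sense
#' heritability \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)}, its
#' approximate standard error from the inverse average-information matrix,
#' and convergence diagnostics.
#'
#' @slot sigmaA2 additive genetic variance.
#' @slot sigmaE2 residual variance.
#' @slot h2 heritability.
#' @slot seH2 delta-method standard error of h2.
#' @slot converged logical convergence flag.
#' @slot nIterations iterations used.
#' @slot logLik restricted log-likelihood at the estimates.
#' @slot aiMatrix final 2x2 average-information matrix (order: sigmaA2, sigmaE2).
#' @seealso [aireml()]
#' @export
setClass("VarianceComponents", representation(
  sigmaA2 = "numeric", sigmaE2 = "numeric", h2 = "numeric", seH2 = "numeric",
  converged = "logical", nIterations = "integer", logLik = "numeric",
  aiMatrix = "matrix"
))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (object@sigmaA2 < 0 || object@sigmaE2 < 0) {
    msg <- c(msg, "variances must be non-negative")
  }
  if (!is.na(object@h2) && (object@h2 < 0 || object@h2 > 1)) {
    msg <- c(msg, "h2 must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Solution of Henderson's mixed model equations
#'
#' Fixed-effect estimates and per-animal (G)EBVs from one solve of the MME,
#' plus solver diagnostics.
#'
#' @slot bHat named fixed-effect estimates (full-rank dummy coding, first
#'   level of each factor absorbed into the intercept).
#' @slot aHat named per-animal predicted breeding values, one entry for every
#'   animal in the relationship structure.
#' @slot diagnostics list: `alpha` (variance ratio used), `nRecords`, `nAnimals`.
#' @seealso [solveMME()]
#' @export
setClass("MmeSolution", representation(
  bHat = "numeric", aHat = "numeric", diagnostics = "list"
))

#' State of the iterative SNP weighting procedure
#'
#' Per-SNP effect estimates and weights after `iteration` rounds of the
#' weighted single-step GWAS loop, with the per-iteration history.
#'
#' @slot iteration iteration counter t.
#' @slot uHat named per-SNP effect estimates from the final iteration.
#' @slot weights named per-SNP weights d_i entering the next iteration
#'   (normalized so their sum equals the SNP count).
#' @slot history list with one element per iteration: data.frame
#'   (snp, u, d) plus the window variance table of that iteration.
#' @seealso [runWssGwas()]
#' @export
setClass("SnpEffectState", representation(
  iteration = "integer", uHat = "numeric", weights = "numeric",
  history = "list"
))

setValidity("SnpEffectState", function(object) {
  msg <- character()
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(object@uHat) != length(object@weights)) {
    msg <- c(msg, "uHat and weights must align")
  }
  if (length(object@weights) &&
      abs(sum(object@weights) - length(object@weights)) > 1e-6) {
    msg <- c(msg, "normalized weights must sum to the SNP count")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a weighted single-step GWAS scan
#'
#' Bundles everything one scan produces: the final SNP-effect state, the
#' per-window variance partition, the variance components used, and the
#' GEBVs of the final iteration.
#'
#' @slot state a [SnpEffectState-class].
#' @slot windows data.frame: `chrom`, `startBp`, `endBp`, `nSnps`,
#'   `gvarPercent` for every SNP-containing window.
#' @slot vc the [VarianceComponents-class] held fixed across iterations.
#' @slot solution final-iteration [MmeSolution-class].
#' @slot params list of scan parameters (window size, iterations, alpha, ...).
#' @seealso [runWssGwas()], [reportRegions()], [plotWindowVariance()]
#' @export
setClass("WssGwasFit", representation(
  state = "SnpEffectState", windows = "data.frame", vc = "VarianceComponents",
  solution = "MmeSolution", params = "list"
))
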