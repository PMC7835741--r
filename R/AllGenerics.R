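#' Accessors for wssgwas classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `pedRecords()` returns the ordered pedigree table, `nAnimals()` the number
#' of animals, `animalIds()` their ids, `dosage()` the dosage matrix,
#' `markerMap()` the marker map, `relMatrix()` the numeric genomic
#' relationship matrix, `alleleFreq()` the allele frequencies it was built
#' from, `varA()`/`varE()`/`heritability()` the variance components,
#' `fixedEffects()`/`breedingValues()` the MME solution, and
#' `snpEffects()`/`snpWeights()`/`windowVariances()` the scan results.
#'
#' @param x an object of the documented class.
#' @return the extracted component; see each method.
#' @name accessors
#' @aliases pedRecords nAnimals animalIds dosage markerMap relMatrix
#'   alleleFreq varA varE heritability fixedEffects breedingValues
#'   snpEffects snpWeights windowVariances
NULL

#' @rdname accessors
#' @export
setGeneric("pedRecords", function(x) standardGeneric("pedRecords"))
#' @rdname accessors
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname accessors
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))
#' @rdname accessors
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @rdname accessors
#' @export
setGeneric("varA", function(x) standardGeneric("varA"))
#' @rdname accessors
#' @export
setGeneric("varE", function(x) standardGeneric("varE"))
#' @rdname accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))
#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setGeneric("breedingValues", function(x) standardGeneric("breedingValues"))
#' @rdname accessors
#' @export
setGeneric("snpEffects", function(x) standardGeneric("snpEffects"))
#' @rdname accessors
#' @export
setGeneric("snpWeights", function(x) standardGeneric("snpWeights"))
#' @rdname accessors
#' @export
setGeneric("windowVariances", function(x) standardGeneric("windowVariances"))

#' @rdname accessors
setMethod("pedRecords", "PigPedigree", function(x) x@records)
#' @rdname accessors
setMethod("nAnimals", "PigPedigree", function(x) nrow(x@records))
#' @rdname accessors
setMethod("animalIds", "PigPedigree", function(x) x@records$id)
#' @rdname accessors
setMethod("nAnimals", "GenotypeData", function(x) nrow(x@dosage))
#' @rdname accessors
setMethod("animalIds", "GenotypeData", function(x) rownames(x@dosage))
#' @rdname accessors
setMethod("dosage", "GenotypeData", function(x) x@dosage)
#' @rdname accessors
setMethod("markerMap", "GenotypeData", function(x) x@map)
#' @rdname accessors
setMethod("relMatrix", "GenomicMatrix", function(x) x@G)
#' @rdname accessors
setMethod("alleleFreq", "GenomicMatrix", function(x) x@p)
#' @rdname accessors
setMethod("varA", "VarianceComponents", function(x) x@sigmaA2)
#' @rdname accessors
setMethod("varE", "VarianceComponents", function(x) x@sigmaE2)
#' @rdname accessors
setMethod("heritability", "VarianceComponents", function(x) x@h2)
#' @rdname accessors
setMethod("fixedEffects", "MmeSolution", function(x) x@bHat)
#' @rdname accessors
setMethod("breedingValues", "MmeSolution", function(x) x@aHat)
#' @rdname accessors
setMethod("snpEffects", "SnpEffectState", function(x) x@uHat)
#' @rdname accessors
setMethod("snpWeights", "SnpEffectState", function(x) x@weights)
#' @rdname accessors
setMethod("snpEffects", "WssGwasFit", function(x) x@state@uHat)
#' @rdname accessors
setMethod("snpWeights", "WssGwasFit", function(x) x@state@weights)
#' @rdname accessors
setMethod("windowVariances", "WssGwasFit", function(x) x@windows)
#' @rdname accessors
setMethod("varA", "WssGwasFit", function(x) x@vc@sigmaA2)
#' @rdname accessors
setMethod("heritability", "WssGwasFit", function(x) x@vc@h2)
#' @rdname accessors
setMethod("breedingValues", "WssGwasFit", function(x) x@solution@aHat)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFounders, "founders,",
      object@nGenerations, "generations, litter size", object@litterSize, "\n")
  cat("  genome:", object@nChromosomes, "chromosomes x",
      sprintf("%.1f Mb,", object@chromLengthBp / 1e6),
      object@nSnpsPerChrom, "SNPs each\n")
  cat("  h2 target:", object@h2Target, " genotyped fraction:",
      object@genotypedFraction, " QTL windows:", nrow(object@qtlWindows),
      " seed:", object@seed, "\n")
})

setMethod("show", "PigPedigree", function(object) {
  rec <- object@records
  founders <- sum(is.na(rec$sire) & is.na(rec$dam))
  cat("PigPedigree with", nrow(rec), "animals (", founders, "founders )\n")
  if ("generation" %in% names(rec)) {
    cat("  generations:", paste(table(rec$generation), collapse = " / "), "\n")
  }
  print(utils::head(rec, 4))
  if (nrow(rec) > 4) cat("  ...", nrow(rec) - 4, "more rows\n")
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "animals x",
      ncol(object@dosage), "SNPs on",
      length(unique(object@map$chrom)), "chromosome(s);",
      sum(is.na(object@dosage)), "missing dosages\n")
})

setMethod("show", "GenomicMatrix", function(object) {
  cat("GenomicMatrix over", nrow(object@G), "genotyped animals,",
      length(object@p), "SNPs\n")
  cat(sprintf("  sum 2p(1-p) = %.3f; mean diag = %.3f; blend alpha = %g\n",
              object@sum2pq, mean(diag(object@G)), object@alpha))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: sigmaA2 = %.4g, sigmaE2 = %.4g, h2 = %.3f (SE %.4f)\n",
    object@sigmaA2, object@sigmaE2, object@h2, object@seH2))
  cat(sprintf("  AIREML %sconverged in %d iterations, logLik = %.3f\n",
              if (object@converged) "" else "NOT ", object@nIterations,
              object@logLik))
})

setMethod("show", "MmeSolution", function(object) {
  cat("MmeSolution:", length(object@bHat), "fixed effects,",
      length(object@aHat), "breeding values\n")
})

setMethod("show", "SnpEffectState", function(object) {
  cat("SnpEffectState after", object@iteration, "iteration(s):",
      length(object@uHat), "SNPs; weight range",
      sprintf("[%.3g, %.3g]\n", min(object@weights), max(object@weights)))
})

setMethod("show", "WssGwasFit", function(object) {
  w <- object@windows
  cat("WssGwasFit:", length(object@state@uHat), "SNPs,",
      nrow(w), "windows of", sprintf("%.1f Mb;", object@params$windowSize / 1e6),
      object@state@iteration, "weighting iteration(s)\n")
  cat(sprintf("  h2 = %.3f; top window: chr%s %.2f-%.2f Mb, gVar = %.2f%%\n",
              object@vc@h2, w$chrom[which.max(w$gvarPercent)],
              w$startBp[which.max(w$gvarPercent)] / 1e6,
              w$endBp[which.max(w$gvarPercent)] / 1e6, max(w$gvarPercent)))
})
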