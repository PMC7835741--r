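## Iterative weighted single-step GWAS: back-solving SNP effects from
## GEBVs, updating/normalizing SNP weights, and partitioning additive
## genetic variance into fixed 0.8 Mb genomic windows.

#' Back-solve SNP effects from genomic breeding values
#'
#' Given the GEBVs of the genotyped animals, SNP effects are recovered as
#' \deqn{\hat u = \frac{1}{\sum_i 2 p_i (1 - p_i)} D Z' G^{-1} \hat g}
#' so that, with the same unblended G built from Z and D,
#' \eqn{Z \hat u = G G^{-1} \hat g = \hat g} exactly.
#'
#' @param gHat GEBVs of the genotyped animals, in G's row order.
#' @param Z centered genotype matrix (genotyped animals x SNPs).
#' @param G a [GenomicMatrix-class] (its weights and scaling are reused);
#'   must be nonsingular, which for an observed-frequency G means it was
#'   blended — see [blendG()].
#' @return named numeric vector of per-SNP allele substitution effects.
#' @export
backsolveSnpEffects <- function(gHat, Z, G) {
  stopifnot(is(G, "GenomicMatrix"))
  if (length(gHat) != nrow(G@G)) stop("gHat must match G's animal order")
  Gig <- tryCatch(solve(G@G, gHat), error = function(e) {
    stop("G is singular; blend it with A22 (blendG) before back-solving")
  })
  u <- G@weights * as.numeric(crossprod(Z, Gig)) / G@sum2pq
  names(u) <- colnames(Z)
  u
}

#' Per-SNP variance weights from estimated effects
#'
#' \deqn{d_i = \hat u_i^2 \, 2 p_i (1 - p_i)} — each SNP's weight is the
#' additive variance its estimated effect explains at its allele frequency.
#'
#' @param uHat per-SNP effect estimates.
#' @param p allele frequencies in (0, 1).
#' @return numeric vector of raw (un-normalized) weights.
#' @export
updateWeights <- function(uHat, p) {
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must lie in (0, 1)")
  if (any(!is.finite(uHat))) stop("non-finite SNP effect")
  uHat^2 * 2 * p * (1 - p)
}

#' Normalize SNP weights to conserve total genetic variance
#'
#' Rescales the new weights so their sum (the trace of D) equals that of
#' the previous iteration — which is the SNP count, since the loop starts
#' from D = I.
#'
#' @param dNew raw weights from [updateWeights()].
#' @param dOld weights of the previous iteration (default all 1).
#' @return normalized weights summing to `sum(dOld)`.
#' @export
normalizeWeights <- function(dNew, dOld = rep(1, length(dNew))) {
  s <- sum(dNew)
  if (s <= 0) stop("all SNP weights are zero; cannot normalize")
  dNew * sum(dOld) / s
}

#' Assign SNPs to consecutive fixed-size genomic windows
#'
#' Chromosomes are cut into non-overlapping bins of `windowSize` bases
#' anchored at the origin, with half-open coordinates `[k*w, (k+1)*w)` on
#' the 1-based bp positions, so a SNP sitting exactly on a boundary falls
#' into the following window. Only SNP-containing windows are reported.
#'
#' @param map marker map (`snp`, `chrom`, `pos`) or a [GenotypeData-class].
#' @param windowSize window width in bases (default 8e5, i.e. 0.8 Mb).
#' @return list with `index` (per-SNP window number) and `windows`
#'   (data.frame `window`, `chrom`, `startBp`, `endBp`, `nSnps`).
#' @export
assignWindows <- function(map, windowSize = 8e5) {
  if (is(map, "GenotypeData")) map <- markerMap(map)
  if (anyNA(map$chrom) || anyNA(map$pos)) stop("unmapped SNP in marker map")
  bin <- map$pos %/% windowSize
  key <- paste(map$chrom, bin, sep = ":")
  uk <- unique(key)
  index <- match(key, uk)
  first <- !duplicated(key)
  windows <- data.frame(
    window = seq_along(uk),
    chrom = map$chrom[first],
    startBp = bin[first] * windowSize,
    endBp = (bin[first] + 1) * windowSize,
    nSnps = as.integer(tabulate(index, nbins = length(uk))),
    stringsAsFactors = FALSE
  )
  list(index = index, windows = windows)
}

#' Genetic variance explained per genomic window
#'
#' For each window the aggregate genotypic value of the genotyped animals,
#' \eqn{a_w = \sum_{j \in w} Z_j \hat u_j}, is computed and its population
#' variance expressed as a percentage of the additive genetic variance:
#' \deqn{gVar_w = \frac{Var(a_w)}{\sigma^2_a} \times 100.}
#' By default the denominator is the empirical variance of the total
#' genomic breeding value \eqn{Z \hat u} (a single whole-genome window then
#' scores exactly 100%); set `denominator = "sigmaA2"` to divide by the
#' REML additive variance instead. Variances use the n (population)
#' convention, which cancels in the default ratio.
#'
#' @param Z centered genotype matrix (genotyped animals x SNPs).
#' @param uHat per-SNP effects aligned with Z's columns.
#' @param windows result of [assignWindows()] for the same SNPs.
#' @param denominator `"genomic"` (default) or `"sigmaA2"`.
#' @param sigmaA2 REML additive variance, required for
#'   `denominator = "sigmaA2"`.
#' @return the `windows` data.frame with a `gvarPercent` column appended.
#' @export
windowVariance <- function(Z, uHat, windows, denominator = c("genomic", "sigmaA2"),
                           sigmaA2 = NULL) {
  denominator <- match.arg(denominator)
  m <- ncol(Z)
  if (length(uHat) != m || length(windows$index) != m) {
    stop("uHat and window index must align with Z's columns")
  }
  popVar <- function(x) mean((x - mean(x))^2)
  U <- Matrix::sparseMatrix(i = seq_len(m), j = windows$index, x = uHat,
                            dims = c(m, nrow(windows$windows)))
  Aw <- as.matrix(Z %*% U) # animals x windows, window genotypic values
  den <- if (denominator == "genomic") {
    popVar(as.numeric(Z %*% uHat))
  } else {
    if (is.null(sigmaA2) || sigmaA2 <= 0) {
      stop("sigmaA2 must be supplied (and positive) for that denominator")
    }
    sigmaA2
  }
  if (den <= 0) stop("zero denominator: all SNP effects are zero")
  out <- windows$windows
  out$gvarPercent <- apply(Aw, 2, popVar) / den * 100
  out
}

#' Select and report candidate QTL regions
#'
#' Windows explaining strictly more than `threshold` percent of the
#' additive genetic variance form the significant set (sorted in
#' descending gVar order). The `topK` windows are additionally extended by
#' `flankBp` on either side, clipped at chromosome bounds when
#' `chromLengths` is given; ties in gVar break toward the lower chromosome,
#' then the lower start position.
#'
#' @param windows window table with `gvarPercent`, from [windowVariance()].
#' @param threshold significance threshold in percent (default 1.0).
#' @param topK number of top windows to extend (default 3).
#' @param flankBp flank added on each side of a top window (default 4e5).
#' @param chromLengths optional named vector of chromosome lengths (bp) for
#'   clipping the extended regions.
#' @return list with `significant` (data.frame), `topRegions` (data.frame
#'   `chrom`, `startBp`, `endBp`, `gvarPercent` after flanking), `regions`
#'   (the same as a `GRanges`), and `totalGvarPercent` (sum over the
#'   significant set).
#' @export
reportRegions <- function(windows, threshold = 1.0, topK = 3, flankBp = 4e5,
                          chromLengths = NULL) {
  if (!nrow(windows)) stop("empty window table")
  if (!is.null(chromLengths)) {
    chromLengths <- setNames(as.numeric(chromLengths), names(chromLengths))
  }
  chromOrd <- suppressWarnings(as.numeric(windows$chrom))
  ord <- order(-windows$gvarPercent, chromOrd, windows$chrom, windows$startBp)
  sig <- windows[ord, , drop = FALSE][windows$gvarPercent[ord] > threshold, ,
                                      drop = FALSE]
  rownames(sig) <- NULL
  top <- windows[ord, , drop = FALSE][seq_len(min(topK, nrow(windows))), ,
                                      drop = FALSE]
  startExt <- pmax(top$startBp - flankBp, 0)
  endExt <- top$endBp + flankBp
  if (!is.null(chromLengths)) {
    lim <- chromLengths[as.character(top$chrom)]
    endExt <- ifelse(is.na(lim), endExt, pmin(endExt, lim))
  }
  topRegions <- data.frame(
    chrom = top$chrom, startBp = startExt, endBp = endExt,
    gvarPercent = top$gvarPercent, stringsAsFactors = FALSE
  )
  gr <- GenomicRanges::GRanges(
    seqnames = topRegions$chrom,
    ranges = IRanges::IRanges(start = topRegions$startBp + 1,
                              end = topRegions$endBp),
    gvarPercent = topRegions$gvarPercent
  )
  if (!is.null(chromLengths)) {
    GenomeInfoDb::seqlengths(gr) <-
      chromLengths[GenomeInfoDb::seqlevels(gr)]
    gr <- GenomicRanges::trim(gr)
  }
  list(significant = sig, topRegions = topRegions, regions = gr,
       totalGvarPercent = sum(sig$gvarPercent))
}

#' Run the iterative weighted single-step GWAS
#'
#' The full scan loop: starting from equal SNP weights (D = I), each
#' iteration (i) rebuilds the weighted genomic matrix G(t) and blends it
#' with A22, (ii) rebuilds H-inverse, (iii) solves the mixed model
#' equations for GEBVs of all animals, (iv) back-solves SNP effects from
#' the genotyped animals' GEBVs, and (v) updates and trace-normalizes the
#' SNP weights. Three iterations are the standard choice. Variance
#' components are estimated once (first-iteration H-inverse) and held fixed
#' across iterations; the final iteration's effects feed the window
#' variance partition.
#'
#' @param ped a [PigPedigree-class] covering all animals.
#' @param geno QC'd, imputation-complete [GenotypeData-class] for the
#'   genotyped subset (ids must appear in the pedigree).
#' @param pheno data.frame with columns `id`, `y`, plus any fixed-effect
#'   columns named in `fixed`.
#' @param fixed character vector of fixed-effect column names in `pheno`
#'   (dummy-coded via [designMatrix()]); `NULL` fits intercept only.
#' @param vc optional [VarianceComponents-class] to reuse; estimated by
#'   [aireml()] when `NULL`.
#' @param nIterations weighting iterations (default 3).
#' @param alpha G blending weight toward A22 (default 0.05).
#' @param windowSize window width in bases (default 8e5).
#' @param denominator denominator convention for [windowVariance()].
#' @return a [WssGwasFit-class].
#' @export
runWssGwas <- function(ped, geno, pheno, fixed = NULL, vc = NULL,
                       nIterations = 3L, alpha = 0.05, windowSize = 8e5,
                       denominator = "genomic") {
  gids <- animalIds(geno)
  if (!all(gids %in% animalIds(ped))) {
    stop("genotyped animal(s) missing from the pedigree")
  }
  if (!all(pheno$id %in% animalIds(ped))) {
    stop("phenotyped animal(s) missing from the pedigree")
  }
  p <- alleleFrequencies(geno)
  Z <- centerDosages(geno, p)
  A <- buildA(ped)
  a22 <- subsetA22(A, gids)
  Ainv <- buildAInverse(ped)
  y <- pheno$y
  X <- if (is.null(fixed)) designMatrix(NULL, n = length(y)) else {
    designMatrix(pheno[, fixed, drop = FALSE])
  }
  win <- assignWindows(markerMap(geno), windowSize)

  m <- ncol(Z)
  d <- rep(1, m)
  history <- vector("list", nIterations)
  sol <- NULL
  u <- NULL
  Gstar <- NULL
  for (t in seq_len(nIterations)) {
    G <- buildG(geno, weights = d, p = p)
    Gstar <- blendG(G, a22$A22, alpha)
    Ginv <- chol2inv(chol(Gstar@G))
    Hinv <- buildHInverse(Ainv, a22$A22inv, Ginv, gids)
    if (t == 1L && is.null(vc)) {
      vc <- aireml(y, X, pheno$id, Hinv)
    }
    sol <- solveMME(y, X, pheno$id, Hinv, vc)
    gHat <- breedingValues(sol)[gids]
    u <- backsolveSnpEffects(gHat, Z, Gstar)
    wv <- windowVariance(Z, u, win, denominator = denominator,
                         sigmaA2 = varA(vc))
    dRaw <- updateWeights(u, p)
    dNew <- normalizeWeights(dRaw, d)
    history[[t]] <- list(
      effects = data.frame(snp = markerMap(geno)$snp, u = unname(u),
                           d = unname(dNew), stringsAsFactors = FALSE),
      windows = wv
    )
    d <- dNew
  }
  state <- new("SnpEffectState", iteration = as.integer(nIterations),
               uHat = u, weights = setNames(d, names(u)), history = history)
  new("WssGwasFit", state = state,
      windows = history[[nIterations]]$windows, vc = vc, solution = sol,
      params = list(windowSize = windowSize, nIterations = nIterations,
                    alpha = alpha, denominator = denominator))
}
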