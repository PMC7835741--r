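## Genotype QC and the (weighted) VanRaden genomic relationship matrix.

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, animals x SNPs, entries 0/1/2 or `NA`;
#'   rownames are animal ids, colnames SNP ids (generated when absent).
#' @param map data.frame with columns `snp`, `chrom`, `pos`; rows are
#'   reordered with the dosage columns so positions sort within chromosome.
#' @return a [GenotypeData-class].
#' @export
genotypeData <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  }
  map$chrom <- as.character(map$chrom)
  ord <- order(suppressWarnings(as.numeric(map$chrom)), map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  new("GenotypeData", dosage = dosage, map = map)
}

#' Counted-allele frequencies
#'
#' Observed frequency of the dosage-counted allele per SNP (missing dosages
#' excluded). Because \eqn{2p(1-p)} is symmetric in \eqn{p \leftrightarrow
#' 1-p}, using the counted allele rather than the literal minor allele
#' leaves the G-matrix scaling unchanged while keeping the centering
#' consistent with the dosage coding.
#'
#' @param geno a [GenotypeData-class] or dosage matrix.
#' @return numeric vector of frequencies, named by SNP.
#' @export
alleleFrequencies <- function(geno) {
  M <- if (is(geno, "GenotypeData")) dosage(geno) else as.matrix(geno)
  p <- colMeans(M, na.rm = TRUE) / 2
  if (any(!is.finite(p))) stop("SNP with no called genotypes")
  p
}

.hweChisqP <- function(n0, n1, n2) {
  ## 1-df chi-square HWE test on genotype counts, no continuity correction
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- n * 2 * p * q
  e2 <- n * p^2
  chisq <- (n0 - e0)^2 / pmax(e0, 1e-300) +
    (n1 - e1)^2 / pmax(e1, 1e-300) +
    (n2 - e2)^2 / pmax(e2, 1e-300)
  ## monomorphic SNPs are vacuously in equilibrium (MAF filter handles them)
  ifelse(p <= 0 | p >= 1, 1, pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Genotype quality control
#'
#' Applies, in order: removal of individuals with call rate < `mindCall`;
#' then of SNPs with call rate < `genoCall`, Hardy-Weinberg chi-square
#' p-value < `hweP`, minor allele frequency < `maf`, and SNPs that are
#' non-autosomal or unmapped (position 0/NA, or chromosome outside
#' `autosomes` when given, otherwise any non-numeric chromosome label such
#' as X/Y/MT or 0). All thresholds are strict inequalities. Remaining
#' missing dosages are imputed by the SNP mean (2p), which is neutral under
#' centering. Running the filter twice with the same thresholds is
#' idempotent.
#'
#' @param geno a [GenotypeData-class].
#' @param mindCall minimum individual call rate (default 0.90).
#' @param genoCall minimum SNP call rate (default 0.90).
#' @param hweP Hardy-Weinberg p-value threshold (default 1e-6).
#' @param maf minor allele frequency threshold (default 0.01).
#' @param autosomes character vector of autosomal chromosome labels;
#'   `NULL` (default) treats any positive numeric label as autosomal.
#' @return list with `geno` (filtered, imputed [GenotypeData-class]) and
#'   `report` (data.frame of counts removed per criterion).
#' @export
qcFilter <- function(geno, mindCall = 0.90, genoCall = 0.90, hweP = 1e-6,
                     maf = 0.01, autosomes = NULL) {
  M <- dosage(geno)
  map <- markerMap(geno)
  if (!length(M)) stop("empty dosage matrix")
  report <- data.frame(criterion = character(), removed = integer(),
                       stringsAsFactors = FALSE)
  note <- function(what, k) {
    rbind(report, data.frame(criterion = what, removed = as.integer(k)))
  }

  indCall <- rowMeans(!is.na(M))
  dropInd <- indCall < mindCall
  report <- note("individual call rate", sum(dropInd))
  M <- M[!dropInd, , drop = FALSE]
  if (!nrow(M)) stop("all individuals removed by call-rate filter")

  snpCall <- colMeans(!is.na(M))
  dropCall <- snpCall < genoCall

  n0 <- colSums(M == 0, na.rm = TRUE)
  n1 <- colSums(M == 1, na.rm = TRUE)
  n2 <- colSums(M == 2, na.rm = TRUE)
  pHwe <- .hweChisqP(n0, n1, n2)
  dropHwe <- !dropCall & pHwe < hweP

  p <- colMeans(M, na.rm = TRUE) / 2
  mafObs <- pmin(p, 1 - p)
  dropMaf <- !dropCall & !dropHwe & mafObs < maf

  chromNum <- suppressWarnings(as.numeric(map$chrom))
  autosomal <- if (is.null(autosomes)) {
    !is.na(chromNum) & chromNum >= 1
  } else {
    map$chrom %in% as.character(autosomes)
  }
  mapped <- !is.na(map$pos) & map$pos > 0
  dropChrom <- !dropCall & !dropHwe & !dropMaf & !(autosomal & mapped)

  report <- note("SNP call rate", sum(dropCall))
  report <- note("Hardy-Weinberg p-value", sum(dropHwe))
  report <- note("minor allele frequency", sum(dropMaf))
  report <- note("non-autosomal or unmapped", sum(dropChrom))

  keep <- !(dropCall | dropHwe | dropMaf | dropChrom)
  if (!any(keep)) stop("all SNPs removed by QC")
  M <- M[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  ## mean imputation (2p) of surviving missing dosages
  nmiss <- sum(is.na(M))
  if (nmiss) {
    pKeep <- colMeans(M, na.rm = TRUE) / 2
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- 2 * pKeep[idx[, 2]]
  }
  report <- note("missing dosages imputed", nmiss)
  rownames(map) <- NULL
  list(geno = new("GenotypeData", dosage = M, map = map), report = report)
}

#' Centered genotype matrix
#'
#' Column-centers the dosages by twice the allele frequency:
#' \eqn{Z_{ij} = m_{ij} - 2 p_j}.
#'
#' @param geno a [GenotypeData-class] or dosage matrix (no missing values).
#' @param p allele frequencies; observed frequencies by default.
#' @return centered numeric matrix (animals x SNPs).
#' @export
centerDosages <- function(geno, p = NULL) {
  M <- if (is(geno, "GenotypeData")) dosage(geno) else as.matrix(geno)
  if (anyNA(M)) stop("missing dosages: run qcFilter() first")
  if (is.null(p)) p <- alleleFrequencies(M)
  sweep(M, 2, 2 * p, "-")
}

#' VanRaden genomic relationship matrix with SNP weights
#'
#' \deqn{G = \frac{Z D Z'}{\sum_i 2 p_i (1 - p_i)}}
#' where Z is the centered dosage matrix and D a diagonal matrix of SNP
#' weights. With D = I this is the unweighted first-iteration G; weighted
#' iterations pass the normalized weights. G is invariant to a uniform
#' rescaling of D that is subsequently trace-normalized.
#'
#' @param geno a [GenotypeData-class] or dosage matrix without missing values.
#' @param weights per-SNP weights (default all 1).
#' @param p allele frequencies used for centering and scaling; observed
#'   frequencies by default.
#' @return a [GenomicMatrix-class].
#' @export
buildG <- function(geno, weights = NULL, p = NULL) {
  M <- if (is(geno, "GenotypeData")) dosage(geno) else as.matrix(geno)
  if (is.null(p)) p <- alleleFrequencies(M)
  m <- ncol(M)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("need one weight per SNP")
  if (any(weights < 0)) stop("SNP weights must be non-negative")
  if (length(p) != m) stop("need one allele frequency per SNP")
  sum2pq <- sum(2 * p * (1 - p))
  if (sum2pq <= 0) stop("sum of 2p(1-p) is zero: monomorphic panel")
  Z <- centerDosages(M, p)
  Zw <- sweep(Z, 2, weights, "*")
  G <- tcrossprod(Zw, Z) / sum2pq
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(M), rownames(M))
  new("GenomicMatrix", G = G, p = unname(p), sum2pq = sum2pq,
      weights = unname(weights), alpha = 0)
}

#' Blend G with the pedigree block A22
#'
#' \eqn{G^* = (1 - \alpha) G + \alpha A_{22}}. The observed-frequency G is
#' always singular (centered rows sum to zero), so a small pedigree blend
#' makes it invertible before entering the H-inverse; `alpha = 0` returns
#' G unchanged.
#'
#' @param G a [GenomicMatrix-class].
#' @param A22 pedigree relationship block over the same animals, same order.
#' @param alpha blending weight in `[0, 1)`; default 0.05.
#' @return a [GenomicMatrix-class] with the blended matrix.
#' @export
blendG <- function(G, A22, alpha = 0.05) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (alpha == 0) return(G)
  A22 <- as.matrix(A22)
  if (!all(dim(A22) == dim(G@G))) stop("dimension mismatch between G and A22")
  Gs <- (1 - alpha) * G@G + alpha * A22
  new("GenomicMatrix", G = Gs, p = G@p, sum2pq = G@sum2pq,
      weights = G@weights, alpha = alpha)
}
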