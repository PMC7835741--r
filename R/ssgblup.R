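## Single-step GBLUP core: the H-inverse matrix, AI-REML variance
## components for the single-trait animal model y = Xb + Za + e, and the
## mixed-model-equation solver for fixed effects and (G)EBVs.

#' Inverse of the combined pedigree-genomic relationship matrix
#'
#' Single-step methods replace A-inverse in the mixed model equations by
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
#' \end{bmatrix}}
#' where the non-zero block sits on the genotyped animals. When G equals
#' A22 (or no animal is genotyped) H-inverse reduces to A-inverse exactly.
#'
#' @param Ainv sparse A-inverse from [buildAInverse()] (dimnames = ids).
#' @param A22inv dense inverse of the genotyped block, from [subsetA22()].
#' @param Ginv dense inverse of the (blended) genomic matrix, same animal
#'   order as `A22inv`; pass `NULL` together with an empty `genotypedIds`
#'   for the no-genomics case.
#' @param genotypedIds ids of the genotyped animals, in the row order of
#'   `Ginv`/`A22inv`.
#' @return sparse symmetric H-inverse with the ordering of `Ainv`.
#' @export
buildHInverse <- function(Ainv, A22inv, Ginv, genotypedIds = rownames(Ginv)) {
  if (length(genotypedIds) == 0) return(Ainv)
  idx <- match(genotypedIds, rownames(Ainv))
  if (anyNA(idx)) stop("genotyped id(s) absent from A-inverse ordering")
  block <- as.matrix(Ginv) - as.matrix(A22inv)
  Tm <- as(as(Ainv, "generalMatrix"), "TsparseMatrix")
  bi <- rep(idx, times = length(idx))
  bj <- rep(idx, each = length(idx))
  Hinv <- Matrix::sparseMatrix(
    i = c(Tm@i + 1L, bi), j = c(Tm@j + 1L, bj),
    x = c(Tm@x, as.numeric(block)),
    dims = dim(Ainv), dimnames = dimnames(Ainv)
  )
  Matrix::forceSymmetric((Hinv + Matrix::t(Hinv)) / 2)
}

#' Full-rank dummy-coded design matrix for fixed effects
#'
#' Builds the X matrix for the animal model from a data.frame of factors
#' (e.g. birth year, sex, farm) with an intercept and the first level of
#' each factor dropped.
#'
#' @param fixed data.frame of covariates, one row per record; factors and
#'   character columns are dummy-coded, numeric columns enter as-is.
#'   `NULL` yields an intercept-only design.
#' @param n number of records (only needed when `fixed` is `NULL`).
#' @return numeric design matrix with an `(Intercept)` column.
#' @export
designMatrix <- function(fixed = NULL, n = NULL) {
  if (is.null(fixed)) {
    if (is.null(n)) stop("need n for an intercept-only design")
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  fixed <- as.data.frame(fixed, stringsAsFactors = FALSE)
  for (j in seq_along(fixed)) {
    if (is.character(fixed[[j]]) || is.logical(fixed[[j]])) {
      fixed[[j]] <- factor(fixed[[j]])
    }
  }
  ## drop constant factors (they are confounded with the intercept)
  keep <- vapply(fixed, function(col) {
    !(is.factor(col) && nlevels(droplevels(col)) < 2)
  }, logical(1))
  fixed <- fixed[, keep, drop = FALSE]
  if (!ncol(fixed)) return(designMatrix(NULL, n = nrow(fixed)))
  X <- model.matrix(~ ., data = droplevels(fixed))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

## Shared MME pieces. animal: character per record; ids: full animal list
## (rownames of Kinv). Returns dense cross-products and the sparse
## incidence Zinc.
.mmeParts <- function(y, X, animal, ids) {
  n <- length(y)
  if (nrow(X) != n || length(animal) != n) {
    stop("y, X and animal must have one entry per record")
  }
  j <- match(as.character(animal), ids)
  if (anyNA(j)) {
    stop("phenotyped animal(s) missing from the relationship structure: ",
         paste(utils::head(unique(animal[is.na(j)]), 5), collapse = ", "))
  }
  q <- length(ids)
  Zinc <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1, dims = c(n, q))
  list(
    Zinc = Zinc, n = n, p = ncol(X), q = q,
    XtX = crossprod(X), XtZ = as.matrix(Matrix::crossprod(X, Zinc)),
    ZtZ = as.matrix(Matrix::crossprod(Zinc)),
    Xty = as.numeric(crossprod(X, y)), Zty = as.numeric(Matrix::crossprod(Zinc, y))
  )
}

## Assemble and factor the MME coefficient matrix for a given variance
## ratio alpha = sigmaE2/sigmaA2, returning the Cholesky factor.
.mmeChol <- function(parts, KinvDense, alpha) {
  p <- parts$p
  q <- parts$q
  M <- matrix(0, p + q, p + q)
  M[1:p, 1:p] <- parts$XtX
  M[1:p, (p + 1):(p + q)] <- parts$XtZ
  M[(p + 1):(p + q), 1:p] <- t(parts$XtZ)
  M[(p + 1):(p + q), (p + 1):(p + q)] <- parts$ZtZ + alpha * KinvDense
  chol(M)
}

.cholSolve <- function(R, rhs) {
  backsolve(R, backsolve(R, rhs, transpose = TRUE))
}

#' AI-REML variance components for the animal model
#'
#' Restricted maximum-likelihood estimation of \eqn{(\sigma^2_a,
#' \sigma^2_e)} for \eqn{y = Xb + Za + e}, \eqn{a \sim N(0, K\sigma^2_a)},
#' by average-information updates computed from the mixed model equations.
#' An update that would leave the parameter space falls back to the EM-REML
#' step for that round; components are floored at `1e-10 * var(y)`.
#' Convergence is declared when the relative change of both components
#' drops below `tol`. The heritability standard error comes from the
#' inverse average-information matrix by the delta method.
#'
#' @param y numeric response vector (one record per row).
#' @param X fixed-effect design matrix (see [designMatrix()]); must be full
#'   column rank.
#' @param animal character vector mapping each record to an animal id.
#' @param Kinv inverse relationship matrix (A-inverse or H-inverse) with
#'   animal ids as dimnames; every phenotyped animal must appear.
#' @param init optional starting values `c(sigmaA2, sigmaE2)`; default
#'   `var(y)/2` for both.
#' @param tol relative-change convergence tolerance (default 1e-8).
#' @param maxIter maximum iterations (default 50); non-convergence is
#'   reported in the returned object, never silently accepted.
#' @param verbose print per-iteration components.
#' @return a [VarianceComponents-class].
#' @export
aireml <- function(y, X, animal, Kinv, init = NULL, tol = 1e-8,
                   maxIter = 50L, verbose = FALSE) {
  ids <- rownames(Kinv)
  if (is.null(ids)) stop("Kinv needs animal ids as dimnames")
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient; use designMatrix()")
  parts <- .mmeParts(y, X, animal, ids)
  KinvDense <- as.matrix(Kinv)
  n <- parts$n
  p <- parts$p
  q <- parts$q
  aidx <- (p + 1):(p + q)
  rhs <- c(parts$Xty, parts$Zty)
  vy <- var(y)
  floorVal <- 1e-10 * vy
  theta <- if (is.null(init)) c(vy / 2, vy / 2) else as.numeric(init)
  if (any(theta <= 0)) stop("starting variances must be positive")
  X <- as.matrix(X)
  Zinc <- parts$Zinc
  AI <- diag(2)
  converged <- FALSE
  iter <- 0L
  Rfinal <- NULL

  Pvec <- function(R, v, se) {
    rv <- c(as.numeric(crossprod(X, v)), as.numeric(Matrix::crossprod(Zinc, v)))
    sv <- .cholSolve(R, rv)
    (v - as.numeric(X %*% sv[1:p]) - as.numeric(Zinc %*% sv[aidx])) / se
  }

  while (iter < maxIter && !converged) {
    iter <- iter + 1L
    sa <- theta[1]
    se <- theta[2]
    alpha <- se / sa
    R <- .mmeChol(parts, KinvDense, alpha)
    sol <- .cholSolve(R, rhs)
    b <- sol[1:p]
    a <- sol[aidx]
    ehat <- y - as.numeric(X %*% b) - as.numeric(Zinc %*% a)
    Cinv <- chol2inv(R)
    trKC <- sum(KinvDense * Cinv[aidx, aidx])
    Za <- as.numeric(Zinc %*% a)

    Sa <- -0.5 * ((q - alpha * trKC) / sa - sum(ehat * Za) / (se * sa))
    Se <- -0.5 * ((n - p - q + alpha * trKC) / se - sum(ehat^2) / se^2)

    fa <- Za / sa
    fe <- ehat / se
    Pfa <- Pvec(R, fa, se)
    Pfe <- Pvec(R, fe, se)
    AI <- 0.5 * matrix(c(sum(fa * Pfa), sum(fa * Pfe),
                         sum(fa * Pfe), sum(fe * Pfe)), 2, 2)

    step <- tryCatch(solve(AI, c(Sa, Se)), error = function(e) rep(NA_real_, 2))
    thetaNew <- theta + step
    if (any(!is.finite(thetaNew)) || any(thetaNew < floorVal)) {
      ## step-halving keeps Newton-like speed toward a boundary optimum
      k <- 1
      while (k > 2^-30 && (any(!is.finite(thetaNew)) ||
                           any(thetaNew < floorVal))) {
        k <- k / 2
        thetaNew <- theta + k * step
      }
      if (any(!is.finite(thetaNew)) || any(thetaNew < floorVal)) {
        ## EM-REML fallback is guaranteed to stay in the parameter space
        aKa <- as.numeric(a %*% (KinvDense %*% a))
        thetaNew <- c((aKa + se * trKC) / q, sum(y * ehat) / (n - p))
      }
      thetaNew <- pmax(thetaNew, floorVal)
    }
    relChange <- max(abs(thetaNew - theta) / pmax(abs(theta), 1e-12))
    if (verbose) {
      message(sprintf("iter %2d: sigmaA2 = %.6g sigmaE2 = %.6g (change %.2e)",
                      iter, thetaNew[1], thetaNew[2], relChange))
    }
    theta <- thetaNew
    Rfinal <- R
    if (relChange < tol) converged <- TRUE
  }

  sa <- theta[1]
  se <- theta[2]
  h2 <- sa / (sa + se)
  covTheta <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  g <- c(se, -sa) / (sa + se)^2
  seH2 <- sqrt(max(0, as.numeric(t(g) %*% covTheta %*% g)))

  ## restricted log-likelihood via the standard MME identities
  R <- .mmeChol(parts, KinvDense, se / sa)
  sol <- .cholSolve(R, rhs)
  ehat <- y - as.numeric(X %*% sol[1:p]) - as.numeric(Zinc %*% sol[aidx])
  yPy <- sum(y * ehat) / se
  ldK <- as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)
  ldM <- 2 * sum(log(diag(R)))
  logLik <- -0.5 * ((n - p - q) * log(se) + q * log(sa) - ldK + ldM + yPy)

  new("VarianceComponents", sigmaA2 = sa, sigmaE2 = se, h2 = h2,
      seH2 = seH2, converged = converged, nIterations = iter,
      logLik = logLik, aiMatrix = AI)
}

#' Solve Henderson's mixed model equations
#'
#' Solves
#' \deqn{\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + K^{-1} \sigma^2_e /
#' \sigma^2_a \end{bmatrix} \begin{bmatrix} \hat b \\ \hat a \end{bmatrix}
#' = \begin{bmatrix} X'y \\ Z'y \end{bmatrix}}
#' for the fixed effects and per-animal (G)EBVs, at fixed variance
#' components. The fixed-effect identifiability constraint is the full-rank
#' dummy coding of [designMatrix()] (first level of each factor dropped).
#'
#' @inheritParams aireml
#' @param vc a [VarianceComponents-class] (or list with `sigmaA2`,
#'   `sigmaE2`), both variances positive.
#' @return an [MmeSolution-class]; `breedingValues()` covers every animal in
#'   `Kinv`, including unphenotyped ancestors.
#' @export
solveMME <- function(y, X, animal, Kinv, vc) {
  sa <- if (is(vc, "VarianceComponents")) vc@sigmaA2 else vc$sigmaA2
  se <- if (is(vc, "VarianceComponents")) vc@sigmaE2 else vc$sigmaE2
  if (sa <= 0 || se <= 0) stop("variances must be positive to solve the MME")
  ids <- rownames(Kinv)
  if (is.null(ids)) stop("Kinv needs animal ids as dimnames")
  parts <- .mmeParts(y, X, animal, ids)
  R <- .mmeChol(parts, as.matrix(Kinv), se / sa)
  sol <- .cholSolve(R, c(parts$Xty, parts$Zty))
  p <- parts$p
  bHat <- setNames(sol[1:p], colnames(X))
  aHat <- setNames(sol[(p + 1):(p + parts$q)], ids)
  new("MmeSolution", bHat = bHat, aHat = aHat,
      diagnostics = list(alpha = se / sa, nRecords = parts$n,
                         nAnimals = parts$q))
}
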