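# Independent oracle implementations used to cross-check the package's
# fast paths. These deliberately use the naive/direct formulations.

# Numerator relationship matrix by the scalar tabular method (plain double
# loop, no vectorization) -- oracle for buildA / buildAInverse.
oracleTabularA <- function(ped) {
  rec <- pedRecords(ped)
  n <- nrow(rec)
  pos <- seq_len(n)
  names(pos) <- rec$id
  s <- unname(pos[rec$sire])
  d <- unname(pos[rec$dam])
  A <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      aij <- 0
      if (!is.na(s[i])) aij <- aij + 0.5 * A[s[i], j]
      if (!is.na(d[i])) aij <- aij + 0.5 * A[d[i], j]
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

# EM-REML for y = Xb + Za + e, a ~ N(0, K sa2), via the direct-V
# formulation (V, P matrices formed explicitly) -- independent of the
# package's MME-based AI-REML.
oracleEmReml <- function(y, X, Zinc, K, init = NULL, tol = 1e-10,
                         maxIter = 2000L) {
  n <- length(y)
  q <- ncol(Zinc)
  ZKZ <- Zinc %*% K %*% t(Zinc)
  theta <- if (is.null(init)) rep(var(y) / 2, 2) else init
  for (it in seq_len(maxIter)) {
    V <- ZKZ * theta[1] + diag(n) * theta[2]
    Vi <- solve(V)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% solve(t(X) %*% ViX, t(ViX))
    Py <- P %*% y
    saNew <- theta[1] + (theta[1]^2 / q) *
      (sum(Py * (ZKZ %*% Py)) - sum(diag(P %*% ZKZ)))
    seNew <- theta[2] + (theta[2]^2 / n) *
      (sum(Py^2) - sum(diag(P)))
    thetaNew <- pmax(c(saNew, seNew), 1e-12)
    delta <- max(abs(thetaNew - theta) / pmax(theta, 1e-12))
    theta <- thetaNew
    if (delta < tol) break
  }
  list(sigmaA2 = theta[1], sigmaE2 = theta[2], iterations = it)
}

# GLS/BLUP oracle: fixed effects by GLS on V, breeding values as
# a_hat = sa2 * K Z' V^-1 (y - X b) -- the direct (non-MME) route.
oracleGlsBlup <- function(y, X, Zinc, K, sa2, se2) {
  n <- length(y)
  V <- Zinc %*% K %*% t(Zinc) * sa2 + diag(n) * se2
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sa2 * K %*% t(Zinc) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b), a = as.numeric(a))
}

# Ridge-regression SNP-BLUP oracle: effects from the SNP-level mixed model
# with shrinkage se2/(sa2/sum2pq), fixed effects absorbed by projection.
oracleSnpBlup <- function(y, X, Z, sa2, se2, sum2pq) {
  Px <- diag(length(y)) - X %*% solve(crossprod(X), t(X))
  Zc <- Px %*% Z
  lambda <- se2 / (sa2 / sum2pq)
  as.numeric(solve(crossprod(Zc) + diag(lambda, ncol(Z)),
                   crossprod(Zc, Px %*% y)))
}

# Restricted log-likelihood evaluated directly from V -- checks the MME
# identity used inside aireml().
oracleRemlLogLik <- function(y, X, Zinc, K, sa2, se2) {
  n <- length(y)
  V <- Zinc %*% K %*% t(Zinc) * sa2 + diag(n) * se2
  Vi <- solve(V)
  ViX <- Vi %*% X
  XtViX <- t(X) %*% ViX
  P <- Vi - ViX %*% solve(XtViX, t(ViX))
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            sum(y * (P %*% y)))
}

# record -> animal incidence matrix as a dense base matrix
denseIncidence <- function(animal, ids) {
  Zinc <- matrix(0, length(animal), length(ids))
  Zinc[cbind(seq_along(animal), match(animal, ids))] <- 1
  Zinc
}
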