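## Numerator relationship matrix machinery: tabular A, Meuwissen-Luo
## inbreeding, Henderson's-rules sparse A-inverse, and the genotyped block
## A22. Unknown parents are treated as unrelated non-inbred founders
## (no genetic groups).

#' Construct a pedigree object
#'
#' Builds a validated [PigPedigree-class] from a data.frame, reordering
#' records if necessary so parents precede offspring (a topological sort;
#' a cycle, i.e. an animal that is its own ancestor, is an error). Unknown
#' parents may be coded `NA`, `""` or `"0"`.
#'
#' @param records data.frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`, `birthYear`, `farm`, `generation`.
#' @return a [PigPedigree-class].
#' @export
pigPedigree <- function(records) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) {
    if (!col %in% names(rec)) stop("pedigree needs column '", col, "'")
    rec[[col]] <- as.character(rec[[col]])
    if (col != "id") rec[[col]][rec[[col]] %in% c("", "0", "NA")] <- NA
  }
  if (anyDuplicated(rec$id)) {
    stop("duplicate animal id(s): ",
         paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  }
  unknown <- setdiff(c(rec$sire, rec$dam), c(rec$id, NA))
  if (length(unknown)) {
    stop("parent id(s) not declared as animals: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ## topological sort (Kahn); cycles leave unplaced animals
  n <- nrow(rec)
  pos <- seq_len(n)
  names(pos) <- rec$id
  si <- pos[rec$sire]
  di <- pos[rec$dam]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  ## stable variant: always emit the lowest original index available, so an
  ## already-ordered pedigree round-trips unchanged
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    i <- min(queue)
    queue <- queue[queue != i]
    order_out <- c(order_out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order_out) < n) {
    stop("pedigree contains a cycle (an animal is its own ancestor)")
  }
  rec <- rec[order_out, , drop = FALSE]
  rownames(rec) <- NULL
  new("PigPedigree", records = rec)
}

## parent indices (NA = unknown) in record order
.parentIdx <- function(ped) {
  rec <- pedRecords(ped)
  pos <- seq_len(nrow(rec))
  names(pos) <- rec$id
  list(s = unname(pos[rec$sire]), d = unname(pos[rec$dam]), ids = rec$id)
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense additive relationship matrix A with `a_ii = 1 + F_i` and off-
#' diagonals by recursive parental averaging. Rows are computed against all
#' earlier animals in one vectorized sweep per animal, so pedigrees of a few
#' thousand animals are handled in seconds.
#'
#' @param ped a [PigPedigree-class].
#' @return symmetric numeric matrix with animal ids as dimnames.
#' @export
buildA <- function(ped) {
  pidx <- .parentIdx(ped)
  n <- length(pidx$ids)
  A <- matrix(0, n, n, dimnames = list(pidx$ids, pidx$ids))
  s <- pidx$s
  d <- pidx$d
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s[i])) row <- row + 0.5 * A[s[i], prev]
      if (!is.na(d[i])) row <- row + 0.5 * A[d[i], prev]
      A[i, prev] <- row
      A[prev, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal F without forming A: for each animal the ancestor
#' contributions L are accumulated youngest-first and
#' \eqn{a_{ii} = \sum_j L_j^2 D_j} with D_j the Mendelian-sampling variance
#' of ancestor j. Founders (and animals with both parents unknown) have
#' F = 0.
#'
#' @param ped a [PigPedigree-class].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  pidx <- .parentIdx(ped)
  n <- length(pidx$ids)
  s <- pidx$s
  d <- pidx$d
  F <- numeric(n)
  Dms <- numeric(n) # Mendelian sampling variance, filled in order
  for (i in seq_len(n)) {
    Fs <- if (is.na(s[i])) NA_real_ else F[s[i]]
    Fd <- if (is.na(d[i])) NA_real_ else F[d[i]]
    Dms[i] <- if (!is.na(s[i]) && !is.na(d[i])) {
      0.5 - 0.25 * (Fs + Fd)
    } else if (!is.na(s[i]) || !is.na(d[i])) {
      0.75 - 0.25 * max(Fs, Fd, na.rm = TRUE)
    } else 1
    if (is.na(s[i]) || is.na(d[i])) {
      F[i] <- 0
      next
    }
    ## a_ii of a hypothetical offspring-less animal i: trace ancestors of i
    L <- numeric(n)
    L[i] <- 1
    touched <- i
    aii <- 0
    while (length(touched)) {
      j <- max(touched)
      touched <- touched[touched != j]
      aii <- aii + L[j]^2 * Dms[j]
      for (p in c(s[j], d[j])) {
        if (!is.na(p)) {
          if (L[p] == 0) touched <- c(touched, p)
          L[p] <- L[p] + 0.5 * L[j]
        }
      }
      L[j] <- 0
    }
    F[i] <- aii - 1
  }
  names(F) <- pidx$ids
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly by Henderson's rules, always accounting for
#' inbreeding via the Meuwissen-Luo F coefficients: each animal contributes
#' \eqn{\alpha_i = 1/D_i} (the inverse Mendelian-sampling variance) to its
#' own diagonal, \eqn{-\alpha_i/2} to animal-parent pairs and
#' \eqn{\alpha_i/4} among its known parents.
#'
#' @param ped a [PigPedigree-class].
#' @param useInbreeding set `FALSE` to ignore inbreeding in the Mendelian
#'   sampling variances (classical Henderson rules; kept as a documented
#'   test-only option).
#' @return sparse symmetric `Matrix::dsCMatrix` with animal ids as dimnames.
#' @export
buildAInverse <- function(ped, useInbreeding = TRUE) {
  pidx <- .parentIdx(ped)
  n <- length(pidx$ids)
  s <- pidx$s
  d <- pidx$d
  F <- if (useInbreeding) unname(inbreeding(ped)) else numeric(n)
  Fs <- ifelse(is.na(s), NA, F[ifelse(is.na(s), 1L, s)])
  Fd <- ifelse(is.na(d), NA, F[ifelse(is.na(d), 1L, d)])
  Dms <- ifelse(!is.na(s) & !is.na(d), 0.5 - 0.25 * (Fs + Fd),
         ifelse(!is.na(s), 0.75 - 0.25 * Fs,
         ifelse(!is.na(d), 0.75 - 0.25 * Fd, 1)))
  alpha <- 1 / Dms
  ii <- vector("list", n)
  jj <- vector("list", n)
  xx <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- c(s[i], d[i])
    pi <- pi[!is.na(pi)]
    ti <- c(i, pi)
    ## contributions: w = (1, -0.5, -0.5) pattern => alpha * w w'
    w <- c(1, rep(-0.5, length(pi)))
    contrib <- alpha[i] * tcrossprod(w)
    idx <- expand.grid(a = seq_along(ti), b = seq_along(ti))
    ii[[i]] <- ti[idx$a]
    jj[[i]] <- ti[idx$b]
    xx[[i]] <- contrib[cbind(idx$a, idx$b)]
  }
  Ainv <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, n), dimnames = list(pidx$ids, pidx$ids)
  )
  Matrix::forceSymmetric(Ainv)
}

#' Genotyped-block of the numerator relationship matrix
#'
#' Extracts the principal submatrix A22 for the genotyped animals, in the
#' order given by `genotypedIds` (the genotype-file order), together with
#' its dense inverse as needed by the H-inverse construction.
#'
#' @param A dense numerator relationship matrix from [buildA()] (dimnames
#'   are animal ids), or a [PigPedigree-class], in which case A is built
#'   internally.
#' @param genotypedIds character vector of genotyped animal ids.
#' @return list with elements `A22` and `A22inv` (dense matrices).
#' @export
subsetA22 <- function(A, genotypedIds) {
  if (is(A, "PigPedigree")) A <- buildA(A)
  missing_ids <- setdiff(genotypedIds, rownames(A))
  if (length(missing_ids)) {
    stop("genotyped id(s) not in pedigree: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  A22 <- A[genotypedIds, genotypedIds, drop = FALSE]
  A22inv <- chol2inv(chol(A22))
  dimnames(A22inv) <- dimnames(A22)
  list(A22 = A22, A22inv = A22inv)
}
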