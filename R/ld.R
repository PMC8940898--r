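#' Empirical LD matrix of a genotype panel
#'
#' Pearson correlation of dosage columns, with the numerical rank computed
#' by eigendecomposition at relative tolerance \code{tol}.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} (or plain sample x
#'   variant dosage matrix) with at least 2 samples and no monomorphic
#'   variants.
#' @param tol relative eigenvalue tolerance for the rank.
#' @return an \linkS4class{LDMatrix}.
#' @export
empiricalLD <- function(genotypes, tol = 1e-8) {
  X <- if (is(genotypes, "GenotypeMatrix")) dosages(genotypes)
       else as.matrix(genotypes)
  if (nrow(X) < 2L) stop("at least 2 samples are required")
  mono <- apply(X, 2L, function(v) max(v) == min(v))
  if (any(mono))
    stop("monomorphic variant(s): ",
         paste(colnames(X)[mono], collapse = ", "))
  Xs <- standardizeDosages(X)
  C <- crossprod(Xs) / nrow(Xs)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(X)))
  dimnames(C) <- list(ids, ids)
  new("LDMatrix", variants = ids, Chat = C, nPanel = nrow(X),
      rank = as.integer(symmetricRank(C, tol)), tol = tol)
}

#' Ledoit-Wolf projected LD matrix
#'
#' Computes the linear shrinkage of the observed LD matrix \eqn{\hat C}
#' toward the scaled identity that minimizes the expected Frobenius distance
#' to the true LD matrix:
#' \deqn{\pi(C) = \frac{b^2 m}{d^2} I + \frac{a^2}{d^2} \hat C}
#' with \eqn{m = \langle \hat C, I\rangle}, \eqn{d^2 = \|\hat C - m I\|^2},
#' \eqn{b^2 = \min(d^2, n^{-2} \sum_k \|X_k X_k^T - \hat C\|^2)} and
#' \eqn{a^2 = d^2 - b^2}, where \eqn{X_k} is the standardized genotype
#' vector of subject \eqn{k}. The Frobenius inner product and norm are
#' normalized by the number of variants, so \eqn{m = 1} for a correlation
#' matrix. When \eqn{d^2} vanishes (the observed matrix already equals the
#' shrinkage target) \eqn{\hat C} is returned unchanged.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} (or sample x variant
#'   dosage matrix) with at least 2 samples.
#' @param tol numerical tolerance for the degenerate \eqn{d^2 = 0} branch.
#' @return a \linkS4class{ProjectedLD}.
#' @examples
#' gt <- simulateGenotypes(200, maf = rep(0.3, 10), seed = 1)
#' pl <- ledoitWolfProject(gt)
#' pl@a2 + pl@b2 - pl@d2   # zero by construction
#' @export
ledoitWolfProject <- function(genotypes, tol = 1e-12) {
  X <- if (is(genotypes, "GenotypeMatrix")) dosages(genotypes)
       else as.matrix(genotypes)
  n <- nrow(X)
  if (n < 2L) stop("at least 2 samples are required")
  p <- ncol(X)
  base <- empiricalLD(X)
  C <- base@Chat
  Xs <- standardizeDosages(X)
  m <- sum(diag(C)) / p                       # <C, I> with 1/p norm; = 1
  d2 <- sum((C - m * diag(p))^2) / p
  # (1/n^2) sum_k ||X_k X_k^T - C||^2, expanded to avoid p x p outer
  # products per subject:
  #   sum_k ||X_k X_k^T||^2 = sum_k (X_k' X_k)^2
  #   sum_k <X_k X_k^T, C>  = sum_k X_k' C X_k
  rq <- rowSums(Xs^2)
  xcx <- rowSums((Xs %*% C) * Xs)
  sumNorm <- (sum(rq^2) - 2 * sum(xcx) + n * sum(C^2)) / p
  b2 <- min(d2, sumNorm / n^2)
  a2 <- d2 - b2
  piC <- if (d2 > tol) {
    (b2 * m / d2) * diag(p) + (a2 / d2) * C
  } else C
  dimnames(piC) <- dimnames(C)
  new("ProjectedLD", base = base, m = m, d2 = d2, b2 = b2, a2 = a2,
      piC = piC)
}

#' LD scores: per-variant row sums of an LD matrix
#'
#' @param x a square matrix, \linkS4class{LDMatrix} or
#'   \linkS4class{ProjectedLD} (row sums of the projected matrix).
#' @return named numeric vector of row sums.
#' @rdname ldScores
#' @export
setMethod("ldScores", "matrix", function(x) {
  if (nrow(x) != ncol(x)) stop("LD matrix must be square")
  rowSums(x)
})

#' @rdname ldScores
#' @export
setMethod("ldScores", "LDMatrix", function(x) ldScores(x@Chat))

#' @rdname ldScores
#' @export
setMethod("ldScores", "ProjectedLD", function(x) ldScores(x@piC))

#' Inverse or Moore-Penrose pseudoinverse of an LD matrix
#'
#' Full-rank symmetric matrices are inverted exactly; rank-deficient ones
#' get the Moore-Penrose pseudoinverse with eigenvalues below
#' \code{tol * max(|eigenvalue|)} treated as zero. The effective rank is
#' returned alongside.
#'
#' @param C symmetric positive semi-definite matrix.
#' @param tol relative eigenvalue tolerance (default \code{1e-8}, the
#'   float64 noise floor for matrices up to a few thousand variants).
#' @return list with elements \code{inv} (the (pseudo)inverse) and
#'   \code{rank}.
#' @examples
#' inverseOrPseudoinverse(matrix(c(1, 1, 1, 1), 2))  # entries 1/4, rank 1
#' @export
inverseOrPseudoinverse <- function(C, tol = 1e-8) {
  if (!isSquareSymmetric(C)) stop("C must be square and symmetric")
  e <- eigen(C, symmetric = TRUE)
  cut <- tol * max(abs(e$values), .Machine$double.eps)
  keep <- abs(e$values) > cut
  q <- sum(keep)
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  inv <- (inv + t(inv)) / 2
  dimnames(inv) <- dimnames(C)
  list(inv = inv, rank = as.integer(q))
}

#' Noise propagation in the inverse LD matrix
#'
#' For an observed matrix \eqn{\hat C = C + \Delta}, the inverse changes by
#' \deqn{\hat C^{-1} - C^{-1} = -(I + C^{-1}\Delta)^{-1} C^{-1} \Delta
#'   C^{-1},}
#' which quantifies how LD-matrix noise propagates into the heritability
#' estimate. This helper evaluates the right-hand side.
#'
#' @param C the reference (true) invertible matrix.
#' @param Chat the observed matrix; \code{Delta = Chat - C}.
#' @return the matrix \eqn{\hat C^{-1} - C^{-1}} computed via the identity.
#' @export
inverseDifference <- function(C, Chat) {
  Delta <- Chat - C
  Cinv <- solve(C)
  -solve(diag(nrow(C)) + Cinv %*% Delta) %*% Cinv %*% Delta %*% Cinv
}
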