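#' Local SNP heritability from GWAS summary statistics
#'
#' Quadratic-form estimator of the trait variance attributable to the
#' variants of one region,
#' \deqn{\hat r^2_L = \frac{\hat\beta^T C^{-1}\hat\beta - q/n}{n - q}\, n,}
#' where \eqn{\hat\beta} are standardized marginal effects (per-SD units,
#' \code{z/sqrt(n)}), \eqn{C} the variant correlation (LD) matrix and, in
#' the rank-adjusted default, \eqn{C^{-1}} is the Moore-Penrose
#' pseudoinverse and \eqn{q = rank(C)} replaces the variant count \eqn{p}.
#' Negative estimates are reported as-is; flooring at zero would bias
#' averages over replicates.
#'
#' @param beta standardized marginal effect vector (\code{z/sqrt(n)}), or a
#'   \linkS4class{GwasSummary} (converted via
#'   \code{\link{standardizedEffects}}).
#' @param ld LD matrix: a numeric matrix, \linkS4class{LDMatrix} or
#'   \linkS4class{ProjectedLD} (the projected matrix is used).
#' @param n GWAS sample size; must exceed the (effective) variant count.
#' @param ldMode provenance label stored on the result: \code{"observed"},
#'   \code{"projected"} or \code{"true"}. Defaults to \code{"projected"}
#'   when \code{ld} is a \linkS4class{ProjectedLD}, else \code{"observed"}.
#' @param rankAdjust if \code{TRUE} (default) substitute \eqn{q = rank(C)}
#'   for \eqn{p} in both the estimator and its variance; \code{FALSE}
#'   reproduces the unadjusted form (requires full rank).
#' @param tol rank tolerance passed to
#'   \code{\link{inverseOrPseudoinverse}}.
#' @return a \linkS4class{HeritabilityEstimate}.
#' @examples
#' estimateLocalH2(c(0, 0), diag(2), n = 100)  # -2/100 * 100/98
#' @export
estimateLocalH2 <- function(beta, ld, n, ldMode = NULL, rankAdjust = TRUE,
                            tol = 1e-8) {
  if (is(beta, "GwasSummary")) beta <- standardizedEffects(beta)
  if (is.null(ldMode))
    ldMode <- if (is(ld, "ProjectedLD")) "projected" else "observed"
  C <- ldMatrix(ld)
  if (length(beta) != nrow(C))
    stop("length of beta must match the LD matrix dimension")
  p <- length(beta)
  pi <- inverseOrPseudoinverse(C, tol = tol)
  q <- if (rankAdjust) pi$rank else p
  if (!rankAdjust && pi$rank < p)
    stop("LD matrix is rank-deficient; use rankAdjust = TRUE")
  if (n <= q)
    stop(sprintf("n (%d) must exceed the effective variant count q (%d)",
                 n, q))
  quad <- drop(crossprod(beta, pi$inv %*% beta))
  r2 <- (quad - q / n) / (n - q) * n
  new("HeritabilityEstimate", r2Local = r2,
      variance = varianceLocalH2(r2, n, q), n = as.integer(n),
      p = as.integer(p), qRank = as.integer(q), ldMode = ldMode)
}

#' Sampling variance of the local heritability estimate
#'
#' \deqn{var(\hat r^2_L) = \left(1 - \frac{p^2}{n^2}\right)^{-1}
#'   \frac{1 - \hat r^2_L}{n}
#'   \left(4 \hat r^2_L + 2 p \frac{1 - \hat r^2_L}{n}\right)}
#' with \eqn{p} replaced by the effective rank when the rank-adjusted
#' estimator is used.
#'
#' The raw formula can turn negative when the point estimate itself is
#' negative (sampling noise below zero); the returned value is floored at
#' zero in that case.
#'
#' @param r2Local the heritability estimate.
#' @param n GWAS sample size.
#' @param pOrQ variant count \eqn{p} or effective rank \eqn{q}.
#' @return the variance (nonnegative).
#' @export
varianceLocalH2 <- function(r2Local, n, pOrQ) {
  stopifnot(n > pOrQ)
  pmax(0,
       (1 - pOrQ^2 / n^2)^-1 * (1 - r2Local) / n *
         (4 * r2Local + 2 * pOrQ * (1 - r2Local) / n))
}

#' Two-SNP closed forms for the local heritability estimator
#'
#' For two variants with correlation \eqn{\rho} the estimator has the
#' printed closed form
#' \deqn{\hat r^2_L = [n(\hat\beta_1^2 + \hat\beta_2^2
#'   - 2\rho\hat\beta_1\hat\beta_2) - 2] / (n - 2)}
#' with LD-perturbation derivative
#' \deqn{\partial \hat r^2_L / \partial\rho
#'   = -2\hat\beta_1\hat\beta_2\, n/(n - 2).}
#' At \eqn{\rho = 1} the matrix is singular and the pseudoinverse branch
#' gives
#' \deqn{\hat r^2_L = [n(\tfrac14\hat\beta_1^2 + \tfrac14\hat\beta_2^2 +
#'   \tfrac12\hat\beta_1\hat\beta_2) - 1]/(n - 1).}
#' These are the published display forms; note that away from
#' \eqn{\rho \in \{0, 1\}} the first expression drops the
#' \eqn{1/(1-\rho^2)} factor that the exact two-SNP inverse carries, so it
#' should be read as the small-\eqn{\rho} form (the general estimator
#' \code{\link{estimateLocalH2}} always uses the exact (pseudo)inverse).
#'
#' @param beta1,beta2 standardized marginal effects.
#' @param rho LD between the two variants; \code{rho = 1} routes to the
#'   pseudoinverse branch.
#' @param n GWAS sample size.
#' @return list with \code{estimate} and \code{dEstimateDRho} (the
#'   derivative; \code{NA} on the singular branch).
#' @export
twoSnpClosedForms <- function(beta1, beta2, rho, n) {
  stopifnot(abs(rho) <= 1, n > 2)
  if (rho == 1) {
    est <- (n * (beta1^2 / 4 + beta2^2 / 4 + beta1 * beta2 / 2) - 1) /
      (n - 1)
    return(list(estimate = est, dEstimateDRho = NA_real_))
  }
  est <- (n * (beta1^2 + beta2^2 - 2 * rho * beta1 * beta2) - 2) / (n - 2)
  list(estimate = est,
       dEstimateDRho = -2 * beta1 * beta2 * n / (n - 2))
}

#' Sensitivity of the local heritability estimate to LD perturbations
#'
#' Reports, per variant pair \eqn{(i, j)}, how the estimate responds to a
#' change in the LD entry \eqn{C_{ij}}. Two conventions are available:
#' \describe{
#'   \item{\code{"gradient"} (default)}{the exact gradient of
#'     \code{\link{estimateLocalH2}} with respect to a symmetric
#'     perturbation of \eqn{(C_{ij}, C_{ji})}:
#'     \eqn{-(C^+\hat\beta)_i (C^+\hat\beta)_j \, n/(n-q)} doubled off the
#'     diagonal. This matches central finite differences of the estimator
#'     and is the convention validated in the tests.}
#'   \item{\code{"quadratic"}}{the published display form
#'     \eqn{\hat\beta_i \hat\beta_j \, n/(n - q)}, the gradient of the
#'     non-inverted quadratic-form representation
#'     \eqn{r^2_L(C) = \hat\beta^T C \hat\beta} with a unit trace
#'     convention for \eqn{tr(\partial\hat C/\partial C_{ij})}.}
#' }
#' The two coincide in magnitude at \eqn{C = I} on the diagonal and differ
#' in general; both are symmetric in \eqn{(i, j)}.
#'
#' @param beta standardized marginal effect vector.
#' @param ld LD matrix (matrix, \linkS4class{LDMatrix} or
#'   \linkS4class{ProjectedLD}).
#' @param n GWAS sample size.
#' @param method \code{"gradient"} or \code{"quadratic"}.
#' @param tol rank tolerance.
#' @return symmetric p x p matrix of sensitivities.
#' @export
ldSensitivity <- function(beta, ld, n, method = c("gradient", "quadratic"),
                          tol = 1e-8) {
  method <- match.arg(method)
  C <- ldMatrix(ld)
  stopifnot(length(beta) == nrow(C))
  pi <- inverseOrPseudoinverse(C, tol = tol)
  q <- pi$rank
  if (n <= q) stop("n must exceed the rank of the LD matrix")
  scale <- n / (n - q)
  if (method == "quadratic") {
    S <- tcrossprod(beta) * scale
  } else {
    b <- drop(pi$inv %*% beta)
    S <- -tcrossprod(b) * scale
    S[upper.tri(S)] <- 2 * S[upper.tri(S)]
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
  }
  dimnames(S) <- dimnames(C)
  S
}
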