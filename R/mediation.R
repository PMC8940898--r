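#' Decompose GWAS marginal effects into mediated and indirect components
#'
#' Conservation identity
#' \eqn{\hat\theta = \hat\theta_{mediated} + \hat\theta_{unmediated}
#'   = \hat\alpha\hat\beta + \hat h}:
#' the expression-mediated component is the causal effect times the eQTL
#' effect; the remainder \eqn{\hat h = \hat\theta - \hat\alpha\hat\beta} is
#' the per-variant indirect effect (heterogeneity, confounding and other
#' non-expression-mediated paths).
#'
#' @param theta GWAS marginal effect vector.
#' @param alpha gene causal-effect estimate (scalar).
#' @param beta eQTL effect vector, harmonized to \code{theta}.
#' @return list with \code{mediated} and \code{indirect} vectors.
#' @export
mediatedDecomposition <- function(theta, alpha, beta) {
  if (length(theta) != length(beta))
    stop("theta and beta must have equal length")
  stopifnot(length(alpha) == 1L)
  mediated <- alpha * beta
  list(mediated = mediated, indirect = theta - mediated)
}

#' Proportion of expression-mediated causal effect explained by a segment
#'
#' The \eqn{\pi_c} statistic: the ratio of rank-corrected quadratic forms
#' of the mediated effect vector \eqn{\hat\alpha\hat\beta} under the
#' reduced (segment-restricted) and full models,
#' \deqn{\pi_c = \frac{\hat\alpha^2 \hat\beta_r^T C^*_r \hat\beta_r -
#'   q_r/n}{\hat\alpha^2 \hat\beta_f^T C^*_f \hat\beta_f - q_f/n}
#'   \cdot \frac{n - q_f}{n - q_r}}
#' where \eqn{C^*} are the projected (Ledoit-Wolf) LD matrices and
#' \eqn{q = rank(C)}. The value is reported unclipped; a flag marks results
#' outside \eqn{[0, 1]}. When the full-model mediated effect is not
#' distinguishable from noise (nonpositive denominator) \eqn{\pi_c} is
#' undefined (\code{NA}, degenerate flag). When \eqn{\hat\alpha = 0} the
#' ratio is driven by the rank terms alone and is flagged degenerate. The
#' per-SNP concentration analog is \eqn{\psi_e = \pi_c\, q_f / q_r}.
#'
#' @param alpha gene causal effect (e.g. from \code{\link{mrJti}}).
#' @param betaFull,betaReduced eQTL effect vectors for the full and
#'   reduced predictor sets.
#' @param ldFull,ldReduced LD for the two sets — preferably
#'   \linkS4class{ProjectedLD} (the projected matrix is used in the
#'   quadratic form and the base-matrix rank in the corrections); plain
#'   matrices are accepted for sensitivity analyses.
#' @param n GWAS sample size.
#' @param theta optional GWAS effect vector over the full set; if given,
#'   the indirect-effect vector is stored on the result.
#' @return a \linkS4class{MediationResult}.
#' @export
piC <- function(alpha, betaFull, betaReduced, ldFull, ldReduced, n,
                theta = NULL) {
  Cf <- ldMatrix(ldFull)
  Cr <- ldMatrix(ldReduced)
  stopifnot(length(betaFull) == nrow(Cf),
            length(betaReduced) == nrow(Cr),
            length(betaReduced) <= length(betaFull))
  qf <- if (is(ldFull, "ProjectedLD")) ldFull@base@rank
        else symmetricRank(Cf)
  qr <- if (is(ldReduced, "ProjectedLD")) ldReduced@base@rank
        else symmetricRank(Cr)
  if (n <= max(qf, qr)) stop("n must exceed both LD ranks")
  num <- alpha^2 * drop(crossprod(betaReduced, Cr %*% betaReduced)) -
    qr / n
  den <- alpha^2 * drop(crossprod(betaFull, Cf %*% betaFull)) - qf / n
  corr <- (n - qf) / (n - qr)
  indirect <- if (is.null(theta)) numeric(0) else
    mediatedDecomposition(theta, alpha, betaFull)$indirect
  if (alpha == 0) {
    # both quadratic forms vanish; the ratio of the pure rank terms is
    # still defined but carries no mediation signal
    val <- (num / den) * corr
    return(new("MediationResult", piC = val, psiE = val * qf / qr,
               alphaHat = alpha, qFull = as.integer(qf),
               qReduced = as.integer(qr), n = as.integer(n),
               indirectEffect = indirect,
               outOfRange = val < 0 || val > 1, degenerate = TRUE,
               note = "alpha = 0: ratio driven by rank terms"))
  }
  if (den <= 0) {
    return(new("MediationResult", piC = NA_real_, psiE = NA_real_,
               alphaHat = alpha, qFull = as.integer(qf),
               qReduced = as.integer(qr), n = as.integer(n),
               indirectEffect = indirect, outOfRange = FALSE,
               degenerate = TRUE,
               note = "mediated effect not distinguishable from noise"))
  }
  val <- (num / den) * corr
  new("MediationResult", piC = val, psiE = val * qf / qr,
      alphaHat = alpha, qFull = as.integer(qf), qReduced = as.integer(qr),
      n = as.integer(n), indirectEffect = indirect,
      outOfRange = val < 0 || val > 1, degenerate = FALSE, note = "")
}
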